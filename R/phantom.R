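#' Specification for one synthetic hand phantom
#'
#' Phantoms emulate the variability of clinical hand radiographs that the
#' preprocessing engine must absorb: variable sizes, white-on-black vs
#' black-on-white grayscale base, optional collimation border and "L"
#' side marker, mild intensity jitter and additive noise. The hand itself
#' is a knuckle-wide trapezoidal palm plus five splayed digit capsules of
#' tissue intensity containing brighter bone bars; each digit bone is
#' interrupted by a dark growth-plate gap whose width shrinks linearly
#' with the bone-age class and closes at 18 years, giving the classifier
#' and the attention maps a localized, age-dependent feature analogous to
#' physeal closure. All hand dimensions scale with the image height, as
#' on a field collimated to the hand.
#'
#' The gap width is `max(0, round(12 * (18 - age) / 13))` pixels at a
#' 512-pixel image height, scaled proportionally for other heights.
#'
#' @param height,width image size in pixels (at least 64 each).
#' @param sex `"female"` or `"male"` (males get a slightly wider hand).
#' @param bone_age_class integer in 5..18.
#' @param white_background if `TRUE` the whole image is inverted so bones
#'   are dark on a white base.
#' @param collimation render a collimation border band.
#' @param marker render a bright "L" annotation marker block.
#' @param bit_depth 8 or 16.
#' @param seed integer; identical specs give pixel-identical phantoms.
#' @return an object of class `phantom_spec`.
#' @export
phantom_spec <- function(height = 512L, width = 410L, sex = "female",
                         bone_age_class = 10L, white_background = FALSE,
                         collimation = FALSE, marker = FALSE,
                         bit_depth = 8L, seed = 1L) {
  sex <- match.arg(sex, c("female", "male"))
  stopifnot(bone_age_class %in% 5:18, bit_depth %in% c(8L, 16L))
  structure(list(height = as.integer(height), width = as.integer(width),
                 sex = sex, bone_age_class = as.integer(bone_age_class),
                 white_background = isTRUE(white_background),
                 collimation = isTRUE(collimation), marker = isTRUE(marker),
                 bit_depth = as.integer(bit_depth), seed = as.integer(seed)),
            class = "phantom_spec")
}

#' Growth-plate gap width for a bone-age class
#'
#' @param bone_age_class integer in 5..18.
#' @param height image height the width is scaled to (512 = reference).
#' @return gap width in pixel rows (0 at 18 years = closed physis).
#' @export
growth_plate_gap <- function(bone_age_class, height = 512L) {
  pmax(0, round(12 * (18 - bone_age_class) / 13 * height / 512))
}

# Nominal intensities as fractions of the dynamic range. Chosen so the
# five classes stay separable under the 2% noise floor, like real
# bone/tissue/background contrast after windowing.
PHANTOM_LEVELS <- c(bone = 0.78, tissue = 0.35, background = 0.04,
                    collimation = 0.22, annotation = 0.95)

#' Generate a synthetic hand radiograph with per-pixel ground truth
#'
#' @param spec a [phantom_spec()].
#' @return list with elements `radiograph` (a [radiograph()]) and `truth`,
#'   where `truth` has `class_map` (integer matrix over the five classes,
#'   in the fixed order bone, tissue, background, collimation, annotation),
#'   `hand_mask` (logical matrix: bone or tissue, largest component), and
#'   `gap_boxes` (data frame of growth-plate gap rectangles, 1-based
#'   inclusive `r0, r1, c0, c1`). The class map is exact: it is emitted
#'   before noise is added and before any background inversion.
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  h <- spec$height; w <- spec$width
  if (h < 64L || w < 64L)
    baa_stop("baa_geometry_error", "phantom needs at least 64x64 pixels")
  with_seed(spec$seed, {
    jit <- function(s) runif(1, -s, s)
    widen <- if (spec$sex == "male") 1.06 else 1.0
    cm <- matrix(3L, h, w)  # background everywhere
    rr <- row(cm); cc <- col(cm)

    if (spec$collimation) {
      band <- pmax(3L, round(0.03 * c(h, w)))
      border <- rr <= band[1] | rr > h - band[1] | cc <= band[2] | cc > w - band[2]
      cm[border] <- 4L
    }

    # The hand fills most of the frame height, as on a collimated
    # clinical radiograph, and keeps fixed anatomical proportions: all
    # hand dimensions scale with the image height (the frame aspect only
    # changes the background margins, it never stretches the hand). The
    # palm is a trapezoid, widest at the knuckle line (breadth ~0.45 h)
    # and narrowing toward the wrist, so all five digits root into its
    # top edge and the hand is one solid component.
    pc <- (0.50 + jit(0.005)) * w
    palm_top <- round((0.50 + jit(0.008)) * h)
    palm_bot <- round(0.78 * h)
    hw_top <- 0.225 * h * widen
    hw_bot <- 0.125 * h * widen
    hw <- rep(0, h)
    pr_rows <- palm_top:palm_bot
    hw[pr_rows] <- hw_top + (hw_bot - hw_top) *
      (pr_rows - palm_top) / (palm_bot - palm_top)
    cm[rr >= palm_top & rr <= palm_bot & abs(cc - pc) <= hw[pmax(rr, 1L)]] <- 2L

    # wrist block with two forearm/carpal bone bars
    wr0 <- round(0.76 * h); wr1 <- round(0.94 * h)
    wc0 <- round(pc - 0.085 * h * widen); wc1 <- round(pc + 0.085 * h * widen)
    cm[rr >= wr0 & rr <= wr1 & cc >= wc0 & cc <= wc1] <- 2L
    for (b in list(c(-0.059, -0.025), c(0.025, 0.059))) {
      cm[rr >= wr0 & rr <= wr1 &
           cc >= round(pc + b[1] * h) & cc <= round(pc + b[2] * h)] <- 1L
    }

    # Five splayed digits: tissue capsule + bone bar + growth-plate gap.
    # Digit breadth ~0.07 h (fixed hand proportions); digits fan outward
    # from the knuckle line as on a positioned hand, so the inter-digit
    # clefts widen toward the tips.
    offsets <- c(-0.192, -0.096, 0, 0.096, 0.192)
    splay <- c(0.08, 0.035, 0, -0.035, -0.08) # column shift per row above base
    tops <- c(0.33, 0.25, 0.21, 0.25, 0.35)   # middle digit ~0.29 h long
    base <- (0.54 + jit(0.005)) * h  # roots overlap the palm top edge
    visible_base <- 0.50 * h   # proximal end of the free finger segment
    gap <- growth_plate_gap(spec$bone_age_class, h)
    gap_boxes <- NULL
    for (f in 1:5) {
      fc <- pc + (offsets[f] * widen + jit(0.004)) * h
      ft <- (tops[f] + jit(0.012)) * h
      sl <- splay[f] * (1 + jit(0.1))
      half_t <- 0.035 * h * widen * (1 + jit(0.04))
      # phalanx shadow ~70% of digit breadth: thin (~2 mm) soft-tissue rim
      half_b <- 0.025 * h * widen
      axis <- fc + sl * (rr - base)  # digit center line, fanning outward
      cap <- rr >= ft & rr <= base & abs(cc - axis) <= half_t
      cm[cap & cm != 4L] <- 2L
      bone <- rr >= ft + 0.008 * h & rr <= 0.68 * h &
        abs(cc - ifelse(rr <= base, axis, fc)) <= half_b
      cm[bone] <- 1L
      # physis: tissue band interrupting the bone bar
      yg <- round(ft + (0.45 + jit(0.01)) * (visible_base - ft))
      if (gap > 0) {
        gsel <- rr >= yg & rr <= yg + gap - 1 &
          abs(cc - ifelse(rr <= base, axis, fc)) <= half_b & cm == 1L
        cm[gsel] <- 2L
        if (any(gsel)) {
          gr <- range(rr[gsel]); gc <- range(cc[gsel])
          gap_boxes <- rbind(gap_boxes,
                             data.frame(r0 = gr[1], r1 = gr[2],
                                        c0 = gc[1], c1 = gc[2]))
        }
      }
    }

    if (spec$marker) {
      mh <- max(6L, round(14 * h / 512)); mw <- max(4L, round(10 * w / 512))
      mr0 <- round(0.06 * h); mc0 <- round(0.80 * w)
      sel <- rr >= mr0 & rr < mr0 + mh & cc >= mc0 & cc < mc0 + mw & cm == 3L
      # "L": vertical stroke plus foot
      stroke <- sel & (cc < mc0 + ceiling(mw / 3) | rr >= mr0 + mh - ceiling(mh / 4))
      cm[stroke] <- 5L
    }

    # render intensities with mild per-phantom contrast jitter, then noise
    maxv <- max_intensity(spec$bit_depth)
    lev <- PHANTOM_LEVELS * c(runif(1, 0.9, 1.1), runif(1, 0.9, 1.1), 1, 1, 1)
    lev <- clip(lev, 0, 0.99)
    img <- matrix(lev[cm], h, w) * maxv
    img <- img + rnorm(h * w, sd = 0.02 * maxv)
    img <- round(clip(img, 0, maxv))
    if (spec$white_background) img <- maxv - img

    hand <- largest_component(cm == 1L | cm == 2L)
    truth <- structure(list(class_map = cm, hand_mask = hand,
                            gap_boxes = gap_boxes), class = "phantom_truth")
    rg <- radiograph(img, bit_depth = spec$bit_depth, sex = spec$sex,
                     bone_age_label = spec$bone_age_class,
                     source_id = sprintf("phantom-%s-%02d-%d", spec$sex,
                                         spec$bone_age_class, spec$seed))
    list(radiograph = rg, truth = truth)
  })
}

# keep only the largest 4-connected TRUE component (no hole filling)
largest_component <- function(mask) {
  lab <- conncomp4(mask)
  if (max(lab) <= 1L) return(mask)
  sizes <- tabulate(lab)
  lab == which.max(sizes)  # first maximum = earliest top-left, row-major
}

#' Generate a phantom cohort across sexes and bone-age classes
#'
#' Produces `n_per_class` phantoms for every (sex, age-class) pair with
#' randomized image sizes, grayscale base, collimation, markers and bit
#' depth, emulating the heterogeneity of a clinical archive.
#'
#' @param n_per_class phantoms per (sex, class) pair (at least 1).
#' @param sexes subset of `c("female", "male")`; an empty set gives an
#'   empty cohort.
#' @param seed integer master seed.
#' @param classes bone-age classes to cover (default 5..18).
#' @param size_range range of source image heights in pixels; the default
#'   spans the typical native resolutions of exported radiographs.
#' @return list of `list(radiograph, truth)` pairs, one per phantom.
#' @export
generate_cohort <- function(n_per_class, sexes = c("female", "male"),
                            seed = 1L, classes = 5:18,
                            size_range = c(512L, 2048L)) {
  if (length(sexes) == 0L) return(list())
  sexes <- match.arg(sexes, c("female", "male"), several.ok = TRUE)
  stopifnot(n_per_class >= 1L)
  specs <- list()
  k <- 0L
  for (sex in sexes) for (cl in classes) for (i in seq_len(n_per_class)) {
    k <- k + 1L
    specs[[k]] <- list(sex = sex, cl = cl, i = i)
  }
  draws <- with_seed(seed, data.frame(
    h = sample(size_range[1]:size_range[2], k, replace = TRUE),
    aspect = runif(k, 0.72, 0.95),
    white = runif(k) < 0.5,
    coll = runif(k) < 0.5,
    mark = runif(k) < 0.5,
    deep = runif(k) < 0.2,
    sub_seed = sample.int(.Machine$integer.max, k)
  ))
  lapply(seq_len(k), function(j) {
    s <- specs[[j]]
    generate_phantom(phantom_spec(
      height = draws$h[j], width = round(draws$h[j] * draws$aspect[j]),
      sex = s$sex, bone_age_class = s$cl,
      white_background = draws$white[j], collimation = draws$coll[j],
      marker = draws$mark[j], bit_depth = if (draws$deep[j]) 16L else 8L,
      seed = draws$sub_seed[j]))
  })
}
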