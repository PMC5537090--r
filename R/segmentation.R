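#' Reconstruct a per-pixel label map by sliding-window patch scoring
#'
#' The detection network is slid across the normalized image with
#' top-left corners at multiples of `stride` (patches fully inside the
#' image). Every pixel accumulates the mean score vector of all patches
#' covering it and is labelled with the argmax class; ties break toward
#' the earlier class in the fixed order bone, tissue, background,
#' collimation, annotation. Border pixels covered by no patch inherit the
#' nearest covered pixel's label.
#'
#' @param image a normalized [radiograph()] (square, black background).
#' @param model a [train_patch_classifier()] result.
#' @param patch_size patch side (must match the model).
#' @param stride sliding-window step in pixels. A stride larger than the
#'   patch size leaves coverage gaps and triggers a warning.
#' @return an integer matrix of class `region_label_map` (values 1..5)
#'   with a `classes` attribute.
#' @export
build_label_map <- function(image, model, patch_size = 32L, stride = 4L) {
  stopifnot(inherits(image, "radiograph"), inherits(model, "patch_classifier"))
  S <- as.integer(patch_size)
  if (S != model$patch_size)
    baa_stop("baa_shape_error", "patch_size does not match the model")
  p <- image$pixels
  H <- nrow(p); W <- ncol(p)
  if (S > H || S > W)
    baa_stop("baa_geometry_error", "patch larger than image")
  if (stride < 1L) baa_stop("baa_geometry_error", "stride must be >= 1")
  if (stride > S)
    baa_warn("baa_coverage_gap",
             "stride exceeds patch size; interior pixels may be unscored")
  x <- p / max_intensity(image$bit_depth)
  sc <- score_grid(model, x, S, as.integer(stride))  # (nr*nc) x 5, col-major
  lab <- aggregate_position_scores(sc, H, W, S, as.integer(stride))
  structure(lab, class = "region_label_map", classes = BAA_CLASSES)
}

# Turn a (nr*nc) x 5 matrix of patch-position scores into a per-pixel label
# matrix: every pixel takes the argmax of the mean score vector of all
# patches covering it (summed-area tables over the position grid); pixels
# covered by no patch inherit the nearest covered pixel's label (the index
# clamping below). Ties go to the earlier class.
aggregate_position_scores <- function(sc, H, W, S, stride) {
  nr <- (H - S) %/% stride + 1L
  nc <- (W - S) %/% stride + 1L
  stopifnot(nrow(sc) == nr * nc)
  # pixel y is covered by position rows i with
  # 1 + (i-1)*stride <= y <= (i-1)*stride + S
  idx_lo <- function(n, npos) clip(ceiling((seq_len(n) - S) / stride) + 1L, 1L, npos)
  idx_hi <- function(n, npos) clip(floor((seq_len(n) - 1L) / stride) + 1L, 1L, npos)
  i1 <- idx_lo(H, nr); i2 <- idx_hi(H, nr)
  j1 <- idx_lo(W, nc); j2 <- idx_hi(W, nc)
  sat <- function(m) {
    cs <- m
    if (nrow(m) > 1L) cs <- apply(m, 2, cumsum)
    cs <- matrix(cs, nrow(m), ncol(m))
    if (ncol(m) > 1L) cs <- t(apply(cs, 1, cumsum))
    padded <- matrix(0, nrow(m) + 1L, ncol(m) + 1L)
    padded[-1, -1] <- matrix(cs, nrow(m), ncol(m))
    padded
  }
  box_sum <- function(padded) {
    padded[i2 + 1L, j2 + 1L, drop = FALSE] - padded[i1, j2 + 1L, drop = FALSE] -
      padded[i2 + 1L, j1, drop = FALSE] + padded[i1, j1, drop = FALSE]
  }
  counts <- box_sum(sat(matrix(1, nr, nc)))
  best_val <- matrix(-Inf, H, W)
  lab <- matrix(1L, H, W)
  for (cl in 1:5) {
    mean_c <- box_sum(sat(matrix(sc[, cl], nr, nc))) / counts
    better <- mean_c > best_val   # strict: ties keep the earlier class
    lab[better] <- cl
    best_val[better] <- mean_c[better]
  }
  lab
}

#' @export
print.region_label_map <- function(x, ...) {
  tab <- tabulate(x, 5L)
  cat(sprintf("<region_label_map> %dx%d: %s\n", nrow(x), ncol(x),
              paste(sprintf("%s=%d", attr(x, "classes"), tab), collapse = " ")))
  invisible(x)
}

#' Collapse a label map to a binary hand grid
#'
#' @param map a [build_label_map()] result (or any 1..5 integer matrix).
#' @return logical matrix, `TRUE` where the label is bone or tissue.
#' @export
labelmap_to_hand <- function(map) {
  m <- unclass(map) == 1L | unclass(map) == 2L
  attributes(m) <- list(dim = dim(map))
  m
}

#' Generate a clean hand mask from a binary hand grid
#'
#' Keeps only the largest 4-connected component (ties broken by the
#' component whose top-left pixel comes first in row-major order) and
#' fills its interior holes, yielding one solid region. Idempotent.
#'
#' @param hand logical matrix from [labelmap_to_hand()].
#' @return logical matrix of class `hand_mask`.
#' @export
generate_mask <- function(hand) {
  if (!any(hand))
    baa_stop("baa_empty_segmentation", "no hand pixels to build a mask from")
  comp <- largest_component(hand)
  # fill holes: background not reachable from the border is interior
  filled <- comp | !border_reachable(!comp)
  structure(filled, class = c("hand_mask", class(filled)))
}

# 4-connected flood fill of `open` from the image border; returns logical
# matrix of reachable open pixels.
border_reachable <- function(open) {
  h <- nrow(open); w <- ncol(open)
  seedmask <- matrix(FALSE, h, w)
  seedmask[c(1L, h), ] <- TRUE
  seedmask[, c(1L, w)] <- TRUE
  lab <- conncomp4(open)
  border_labels <- unique(lab[seedmask & open])
  out <- matrix(FALSE, h, w)
  if (length(border_labels)) out <- matrix(lab %in% border_labels, h, w)
  out
}

#' Standardize a masked radiograph (vision pipeline)
#'
#' Applies the post-segmentation stages in order: artifact removal
#' (pixels outside the mask set to zero), translation of the masked
#' content so its bounding-box center coincides with the image center,
#' histogram equalization computed over in-mask pixels only, a 3x3 median
#' denoise, and unsharp-mask sharpening (amount 1, sigma 1), the filters
#' applied within the mask. Output shape equals input shape and the
#' background stays exactly zero.
#'
#' @param image a [radiograph()].
#' @param mask a [generate_mask()] result of the same shape.
#' @return a [radiograph()]; the translated mask is attached as
#'   attribute `"mask"`.
#' @export
vision_pipeline <- function(image, mask) {
  stopifnot(inherits(image, "radiograph"))
  if (!all(dim(mask) == dim(image$pixels)))
    baa_stop("baa_shape_error", "image and mask shapes differ")
  if (!any(mask)) baa_stop("baa_empty_segmentation", "mask is empty")
  maxv <- max_intensity(image$bit_depth)
  p <- image$pixels
  p[!mask] <- 0L

  # center the bounding box of the mask on the image center
  h <- nrow(p); w <- ncol(p)
  rr <- range(which(rowSums(mask) > 0))
  cr <- range(which(colSums(mask) > 0))
  shift <- round(c((h + 1) / 2 - mean(rr), (w + 1) / 2 - mean(cr)))
  p <- shift_matrix(p, shift[1], shift[2], 0L)
  m <- shift_matrix(mask, shift[1], shift[2], FALSE)

  # in-mask histogram equalization (constant regions stay constant)
  v <- p[m]
  u <- sort(unique(v))
  if (length(u) > 1L) {
    cdf <- cumsum(tabulate(match(v, u), length(u))) / length(v)
    cdf0 <- cdf[1]
    newv <- round((cdf - cdf0) / (1 - cdf0) * maxv)
    p[m] <- newv[match(v, u)]
  }

  # 3x3 median denoise then unsharp sharpening, within the mask
  img01 <- p / maxv
  med <- median3x3(img01)
  img01[m] <- med[m]
  blur <- EBImage::imageData(EBImage::gblur(EBImage::as.Image(img01), sigma = 1))
  sharp <- img01 + (img01 - blur)
  img01[m] <- sharp[m]
  out <- round(clip(img01, 0, 1) * maxv)
  out[!m] <- 0
  image$pixels <- matrix(as.integer(out), h, w)
  attr(image, "mask") <- m
  attr(image, "shift") <- shift   # (rows, cols) translation applied
  image
}

# 3x3 median filter via the classic 19-comparison sorting network,
# vectorized over the whole image (replicate padding at the border).
median3x3 <- function(m) {
  h <- nrow(m); w <- ncol(m)
  ri <- list(c(1L, seq_len(h - 1L)), seq_len(h), c(seq_len(h - 1L) + 1L, h))
  ci <- list(c(1L, seq_len(w - 1L)), seq_len(w), c(seq_len(w - 1L) + 1L, w))
  med3 <- function(a, b, c) pmax(pmin(a, b), pmin(pmax(a, b), c))
  lo <- hi <- md <- vector("list", 3L)
  for (j in 1:3) {
    a <- m[ri[[1]], ci[[j]]]; b <- m[ri[[2]], ci[[j]]]; c <- m[ri[[3]], ci[[j]]]
    lo[[j]] <- pmin(a, b, c)
    hi[[j]] <- pmax(a, b, c)
    md[[j]] <- med3(a, b, c)
  }
  med3(pmax(lo[[1]], lo[[2]], lo[[3]]),
       med3(md[[1]], md[[2]], md[[3]]),
       pmin(hi[[1]], hi[[2]], hi[[3]]))
}

shift_matrix <- function(m, dr, dc, fill) {
  h <- nrow(m); w <- ncol(m)
  out <- matrix(fill, h, w)
  src_r <- seq_len(h) - dr
  src_c <- seq_len(w) - dc
  ok_r <- src_r >= 1L & src_r <= h
  ok_c <- src_c >= 1L & src_c <= w
  out[ok_r, ok_c] <- m[src_r[ok_r], src_c[ok_c]]
  out
}
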