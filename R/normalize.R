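#' Normalize the grayscale base to a black background
#'
#' Computes the pixel means of the four 10x10 corner patches and compares
#' their average with half the dynamic-range maximum (128 at 8 bits). If
#' the corners are brighter than that threshold the image is judged to be
#' white-background and every pixel `v` is replaced by `maxval - v`;
#' otherwise the image is returned unchanged. Applying the filter twice
#' is the same as applying it once.
#'
#' @param r a [radiograph()], at least 10x10.
#' @return a black-background [radiograph()].
#' @export
normalize_grayscale_base <- function(r) {
  stopifnot(inherits(r, "radiograph"))
  p <- r$pixels
  if (nrow(p) < 10L || ncol(p) < 10L)
    baa_stop("baa_geometry_error", "image must be at least 10x10")
  if (mean(corner_means(p)) > 2^r$bit_depth / 2) {
    r$pixels <- max_intensity(r$bit_depth) - p
    storage.mode(r$pixels) <- "integer"
  }
  r
}

corner_means <- function(p) {
  h <- nrow(p); w <- ncol(p)
  c(mean(p[1:10, 1:10]), mean(p[1:10, (w - 9):w]),
    mean(p[(h - 9):h, 1:10]), mean(p[(h - 9):h, (w - 9):w]))
}

#' Normalize image size to a zero-padded square
#'
#' The content is scaled (bilinear) so its larger dimension equals
#' `target` with the aspect ratio preserved; the remaining rows or
#' columns are zero-padded symmetrically. Run after
#' [normalize_grayscale_base()] so the padding matches the background.
#'
#' @param r a black-background [radiograph()].
#' @param target output side length (512, the working resolution of the
#'   detection stage).
#' @return a `target x target` [radiograph()].
#' @export
normalize_size <- function(r, target = 512L) {
  stopifnot(inherits(r, "radiograph"))
  p <- r$pixels
  h <- nrow(p); w <- ncol(p)
  f <- target / max(h, w)
  nh <- if (h >= w) target else round(h * f)
  nw <- if (w > h) target else round(w * f)
  maxv <- max_intensity(r$bit_depth)
  if (nh == h && nw == w) {
    content <- p
  } else {
    img <- EBImage::resize(EBImage::as.Image(p / maxv), w = nh, h = nw,
                           filter = "bilinear")
    content <- round(clip(EBImage::imageData(img), 0, 1) * maxv)
  }
  out <- matrix(0L, target, target)
  r0 <- (target - nh) %/% 2L
  c0 <- (target - nw) %/% 2L
  out[r0 + seq_len(nh), c0 + seq_len(nw)] <- as.integer(content)
  r$pixels <- out
  r
}

#' Normalize a phantom and its ground truth consistently
#'
#' Applies [normalize_grayscale_base()] and [normalize_size()] to the
#' radiograph and transforms the ground-truth class map with the same
#' geometry (nearest-neighbour resampling, background padding) so patch
#' sampling and segmentation scoring can be evaluated at the working
#' resolution.
#'
#' @param phantom a `list(radiograph, truth)` pair from [generate_phantom()].
#' @param target output side length.
#' @return a `list(radiograph, truth)` pair at `target x target`.
#' @export
normalize_phantom <- function(phantom, target = 512L) {
  rg <- normalize_size(normalize_grayscale_base(phantom$radiograph), target)
  cm <- phantom$truth$class_map
  h <- nrow(cm); w <- ncol(cm)
  f <- target / max(h, w)
  nh <- if (h >= w) target else round(h * f)
  nw <- if (w > h) target else round(w * f)
  cm2 <- cm[nn_index(h, nh), nn_index(w, nw), drop = FALSE]
  out <- matrix(3L, target, target)  # padding is background class
  r0 <- (target - nh) %/% 2L
  c0 <- (target - nw) %/% 2L
  out[r0 + seq_len(nh), c0 + seq_len(nw)] <- cm2
  gb <- phantom$truth$gap_boxes
  if (!is.null(gb)) {
    gb <- data.frame(r0 = floor((gb$r0 - 1) * f) + 1 + r0,
                     r1 = ceiling(gb$r1 * f) + r0,
                     c0 = floor((gb$c0 - 1) * f) + 1 + c0,
                     c1 = ceiling(gb$c1 * f) + c0)
  }
  truth <- structure(list(class_map = out,
                          hand_mask = largest_component(out == 1L | out == 2L),
                          gap_boxes = gb), class = "phantom_truth")
  list(radiograph = rg, truth = truth)
}
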