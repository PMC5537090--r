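#' Default real-time augmentation configuration
#'
#' Four transform grids with per-transform enable switches. The defaults
#' enumerate: rotation -30..+30 degrees in 1-degree steps (61 values),
#' width scale 0.85..0.99 and height scale 0.90..0.99 in 0.01 steps
#' (15 x 10 = 150 resize combinations), shear x and y angles -5..+5
#' degrees in 1-degree steps (11 x 11 = 121), and the pixel transform
#' `v -> alpha * v + beta` with alpha 0.90..0.99 in 0.01 steps and
#' integer beta 1..10 (10 x 10 = 100). Horizontal flips and translations
#' are never applied: bone-age radiographs are left hands by convention
#' and the preprocessing engine already centers the content.
#'
#' @param rotation_degrees,width_scales,height_scales,shear_x_degrees,shear_y_degrees,alphas,betas
#'   ordered numeric grids overriding the defaults.
#' @param enabled named logical vector over
#'   `c("rotate", "resize", "shear", "pixel")`.
#' @param switch_prob probability that an enabled transform is actually
#'   applied in a stochastic training draw (see [draw_augmentation()]).
#' @return an object of class `augmentation_config`.
#' @export
default_augmentation_config <- function(
    rotation_degrees = seq(-30, 30, by = 1),
    width_scales = seq(0.85, 0.99, by = 0.01),
    height_scales = seq(0.90, 0.99, by = 0.01),
    shear_x_degrees = seq(-5, 5, by = 1),
    shear_y_degrees = seq(-5, 5, by = 1),
    alphas = seq(0.90, 0.99, by = 0.01),
    betas = 1:10,
    enabled = c(rotate = TRUE, resize = TRUE, shear = TRUE, pixel = TRUE),
    switch_prob = 0.5) {
  stopifnot(all(c("rotate", "resize", "shear", "pixel") %in% names(enabled)),
            switch_prob >= 0, switch_prob <= 1)
  structure(list(rotation_degrees = rotation_degrees,
                 width_scales = width_scales, height_scales = height_scales,
                 shear_x_degrees = shear_x_degrees,
                 shear_y_degrees = shear_y_degrees,
                 alphas = alphas, betas = betas,
                 enabled = enabled[c("rotate", "resize", "shear", "pixel")],
                 switch_prob = switch_prob),
            class = "augmentation_config")
}

#' Number of distinct synthetic images one input can become
#'
#' The product of the enabled transforms' grid sizes: resize counts
#' `|width| * |height|`, shear `|x| * |y|`, the pixel transform
#' `|alpha| * |beta|`; a disabled transform contributes a factor of 1.
#' Under the default grids this is 61 * 150 * 121 * 100 = 110,715,000.
#'
#' @param config an [default_augmentation_config()] object.
#' @return integer-valued numeric count.
#' @export
augmentation_cardinality <- function(config) {
  stopifnot(inherits(config, "augmentation_config"))
  e <- config$enabled
  f <- c(
    if (e[["rotate"]]) length(config$rotation_degrees) else 1,
    if (e[["resize"]]) length(config$width_scales) * length(config$height_scales) else 1,
    if (e[["shear"]]) length(config$shear_x_degrees) * length(config$shear_y_degrees) else 1,
    if (e[["pixel"]]) length(config$alphas) * length(config$betas) else 1)
  prod(f)
}

#' @export
print.augmentation_config <- function(x, ...) {
  cat(sprintf(paste0("<augmentation_config> rotate %d | resize %dx%d | ",
                     "shear %dx%d | pixel %dx%d -> %s combinations\n"),
              length(x$rotation_degrees), length(x$width_scales),
              length(x$height_scales), length(x$shear_x_degrees),
              length(x$shear_y_degrees), length(x$alphas), length(x$betas),
              format(augmentation_cardinality(x), big.mark = ",")))
  invisible(x)
}

#' Draw one augmentation parameter set
#'
#' Samples one value uniformly and independently from each enabled grid.
#' With `switches = TRUE` each enabled transform is additionally applied
#' only with probability `config$switch_prob` (the stochastic
#' per-transform switch used by the training stream) and takes its
#' identity value otherwise. Disabled transforms always take identity
#' values (0 degrees rotation/shear, scale 1, alpha 1, beta 0).
#'
#' @param config an [default_augmentation_config()] object.
#' @param switches apply the stochastic per-transform switches.
#' @return an object of class `augmentation_draw`.
#' @export
draw_augmentation <- function(config, switches = FALSE) {
  stopifnot(inherits(config, "augmentation_config"))
  e <- config$enabled
  on <- e
  if (switches) on <- e & (runif(4) < config$switch_prob)
  pick <- function(grid) grid[sample.int(length(grid), 1L)]
  d <- list(
    rotation = if (on[["rotate"]]) pick(config$rotation_degrees) else 0,
    width_scale = if (on[["resize"]]) pick(config$width_scales) else 1,
    height_scale = if (on[["resize"]]) pick(config$height_scales) else 1,
    shear_x = if (on[["shear"]]) pick(config$shear_x_degrees) else 0,
    shear_y = if (on[["shear"]]) pick(config$shear_y_degrees) else 0,
    alpha = if (on[["pixel"]]) pick(config$alphas) else 1,
    beta = if (on[["pixel"]]) pick(config$betas) else 0)
  structure(d, class = "augmentation_draw")
}

#' Apply an augmentation draw to an image
#'
#' The geometric part is composed into a single affine transform
#' (rotation after shear after anisotropic scale, all about the image
#' center) and applied with bilinear resampling and zero fill; the pixel
#' transform `v -> clip(alpha * v + beta, 0, maxval)` follows. An
#' identity draw returns the input unchanged (no resampling is
#' performed). Output shape always equals input shape.
#'
#' @param image a [radiograph()] (or plain numeric matrix, returned as
#'   matrix).
#' @param d an [draw_augmentation()] result.
#' @return augmented image of the same type and shape.
#' @export
apply_augmentation <- function(image, d) {
  stopifnot(inherits(d, "augmentation_draw"))
  is_rg <- inherits(image, "radiograph")
  p <- if (is_rg) image$pixels else image
  maxv <- if (is_rg) max_intensity(image$bit_depth) else max(1, max(p))
  geom_id <- d$rotation == 0 && d$shear_x == 0 && d$shear_y == 0 &&
    d$width_scale == 1 && d$height_scale == 1
  if (!geom_id) {
    A <- affine_about_center(dim(p), d)
    img <- EBImage::affine(EBImage::as.Image(p / maxv), A,
                           filter = "bilinear", bg.col = 0,
                           output.dim = dim(p))
    p <- clip(EBImage::imageData(img), 0, 1) * maxv
  }
  if (d$alpha != 1 || d$beta != 0) p <- d$alpha * p + d$beta
  p <- clip(p, 0, maxv)
  if (is_rg) {
    image$pixels <- matrix(as.integer(round(p)), nrow(p), ncol(p))
    image
  } else p
}

# 3x2 affine matrix (EBImage convention: output = c(x, y, 1) %*% m) for
# rotation %*% shear %*% scale about the image center. Coordinate axis 1
# is the image row (height), axis 2 the column (width).
affine_about_center <- function(dims, d) {
  th <- d$rotation * pi / 180
  R <- matrix(c(cos(th), -sin(th), sin(th), cos(th)), 2, 2)
  Sh <- matrix(c(1, tan(d$shear_y * pi / 180),
                 tan(d$shear_x * pi / 180), 1), 2, 2)
  Sc <- diag(c(d$height_scale, d$width_scale))
  A <- R %*% Sh %*% Sc
  ctr <- dims / 2
  t_vec <- ctr - as.numeric(A %*% ctr)
  rbind(t(A), t_vec)
}

#' Streaming augmentation function for training
#'
#' Returns a closure mapping a `[0, 1]` intensity matrix to an augmented
#' matrix, drawing fresh stochastic switches per call; used as the
#' on-the-fly augmentation hook of the training loop so augmented images
#' are never materialized to disk.
#'
#' @param config an [default_augmentation_config()] object.
#' @return `function(matrix) -> matrix`.
#' @export
augmentation_stream <- function(config) {
  force(config)
  function(m) {
    d <- draw_augmentation(config, switches = TRUE)
    # pixel beta is on the 8-bit scale; rescale for unit-range inputs
    d$beta <- d$beta / 255
    apply_augmentation(m, d)
  }
}
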