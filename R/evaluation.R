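#' Classification evaluation report
#'
#' Computes top-1 accuracy, within-1-year and within-2-year accuracy
#' (fraction of cases with `|pred - truth| <= k`), RMSE in years and,
#' when class probabilities are supplied, mean average precision (the
#' unweighted mean over classes present in the truth of one-vs-rest
#' average precision with all-points interpolation, cases ranked by the
#' class's predicted probability).
#'
#' @param predictions integer predicted bone-age classes.
#' @param truths integer ground-truth classes, same length.
#' @param probabilities optional `n x 14` matrix of class probabilities
#'   (columns ordered over ages 5..18).
#' @param classes class values the probability columns refer to.
#' @return an object of class `baa_eval` with fields `top1_accuracy`,
#'   `within1_accuracy`, `within2_accuracy`, `rmse`, `map` (or `NA`),
#'   `n`.
#' @export
evaluate_predictions <- function(predictions, truths, probabilities = NULL,
                                 classes = BAA_AGE_CLASSES) {
  if (length(predictions) != length(truths) || length(truths) < 1L)
    baa_stop("baa_shape_error", "predictions and truths must have equal length >= 1")
  err <- abs(predictions - truths)
  map <- NA_real_
  if (!is.null(probabilities)) {
    probabilities <- as.matrix(probabilities)
    if (nrow(probabilities) != length(truths) ||
        ncol(probabilities) != length(classes))
      baa_stop("baa_shape_error", "probabilities must be n x length(classes)")
    ap <- vapply(which(classes %in% unique(truths)), function(ci) {
      average_precision(truths == classes[ci], probabilities[, ci])
    }, numeric(1))
    map <- mean(ap)
  }
  structure(list(top1_accuracy = mean(err == 0),
                 within1_accuracy = mean(err <= 1),
                 within2_accuracy = mean(err <= 2),
                 rmse = sqrt(mean(err^2)),
                 map = map, n = length(truths)),
            class = "baa_eval")
}

# one-vs-rest average precision, all-points interpolation: mean of the
# precision at each positive's rank, cases sorted by descending score
# (stable order on ties).
average_precision <- function(is_pos, scores) {
  ord <- order(scores, decreasing = TRUE)
  hits <- is_pos[ord]
  prec_at <- cumsum(hits) / seq_along(hits)
  mean(prec_at[hits])
}

#' @export
print.baa_eval <- function(x, ...) {
  cat(sprintf(paste0("<baa_eval> n=%d  top1 %.2f%%  within-1y %.2f%%  ",
                     "within-2y %.2f%%  RMSE %.2f y%s\n"),
              x$n, 100 * x$top1_accuracy, 100 * x$within1_accuracy,
              100 * x$within2_accuracy, x$rmse,
              if (is.finite(x$map)) sprintf("  mAP %.2f%%", 100 * x$map) else ""))
  invisible(x)
}

#' Mean Intersection over Union of binary masks
#'
#' @param predicted_masks,truth_masks lists of logical matrices, paired.
#' @return mean over pairs of `|A intersect B| / |A union B|`.
#' @export
miou <- function(predicted_masks, truth_masks) {
  stopifnot(length(predicted_masks) == length(truth_masks),
            length(truth_masks) >= 1L)
  ious <- vapply(seq_along(truth_masks), function(i) {
    a <- predicted_masks[[i]]; b <- truth_masks[[i]]
    if (!all(dim(a) == dim(b)))
      baa_stop("baa_shape_error", "mask shapes differ within a pair")
    uni <- sum(a | b)
    if (uni == 0L)
      baa_stop("baa_undefined_iou", "both masks empty: IoU undefined")
    sum(a & b) / uni
  }, numeric(1))
  mean(ious)
}

#' Patch-size / stride sweep of the preprocessing engine
#'
#' For each patch size a detector is trained by `detector_trainer`, then
#' for each stride the full segmentation (label map, hand collapse,
#' largest-component mask) is run over the corpus and scored as mIoU
#' against the ground-truth hand masks. The default grids reproduce the
#' 4 strides x 7 patch sizes = 28-cell table of the selection experiment.
#'
#' @param corpus list of normalized `list(radiograph, truth)` pairs.
#' @param detector_trainer `function(patch_size) -> patch_classifier`.
#' @param strides integer stride grid.
#' @param patch_sizes integer patch-size grid.
#' @return data frame with columns `patch_size`, `stride`, `miou`.
#' @export
patch_stride_sweep <- function(corpus, detector_trainer,
                               strides = c(2L, 4L, 8L, 16L),
                               patch_sizes = c(16L, 24L, 32L, 40L, 48L, 56L, 64L)) {
  out <- data.frame()
  truth_masks <- lapply(corpus, function(p) p$truth$hand_mask)
  for (ps in patch_sizes) {
    model <- detector_trainer(ps)
    for (st in strides) {
      preds <- lapply(corpus, function(p) {
        lm <- build_label_map(p$radiograph, model, patch_size = ps, stride = st)
        generate_mask(labelmap_to_hand(lm))
      })
      out <- rbind(out, data.frame(patch_size = ps, stride = st,
                                   miou = miou(preds, truth_masks)))
    }
  }
  out
}

#' Occlusion-sensitivity attention map
#'
#' Slides a zero-filled square occluder across the input at a fixed
#' stride; at each position the image is re-classified and the map
#' records `p_target(original) - p_target(occluded)`. Positive values
#' mark regions whose occlusion hurts the target class — the regions the
#' classifier relies on.
#'
#' @param model a trained `baa_classifier`.
#' @param image preprocessed [radiograph()] or `[0,1]` matrix.
#' @param occluder_size occluder side length in input (224-scale) pixels.
#' @param occluder_stride occluder step.
#' @param target_class bone-age class whose probability is tracked;
#'   defaults to the image's label if present, else the model's top-1.
#'   A warning (not an error) is raised when the model misclassifies the
#'   image.
#' @return an object of class `attention_map`: `values` (matrix over
#'   occluder positions), `row_offsets`/`col_offsets` (0-based top-left
#'   offsets), `occluder_size`, `occluder_stride`, `target_class`.
#' @export
occlusion_map <- function(model, image, occluder_size = 16L,
                          occluder_stride = 8L, target_class = NULL) {
  stopifnot(inherits(model, "baa_classifier"))
  x <- classifier_input(image)
  n <- nrow(x)
  S <- as.integer(occluder_size)
  if (S > n) baa_stop("baa_geometry_error", "occluder larger than image")
  if (is.null(target_class)) {
    if (inherits(image, "radiograph") && !is.null(image$bone_age_label))
      target_class <- image$bone_age_label
  }
  p0 <- as.numeric(nn_predict_probs(model$net, array(x, c(n, n, 1L, 1L))))
  if (is.null(target_class)) target_class <- BAA_AGE_CLASSES[which.max(p0)]
  ti <- match(target_class, BAA_AGE_CLASSES)
  if (which.max(p0) != ti)
    baa_warn("baa_misclassified",
             "image is not correctly classified; attention map may be diffuse")
  offs <- seq(0L, n - S, by = as.integer(occluder_stride))
  npos <- length(offs)^2
  vals <- matrix(0, length(offs), length(offs))
  # batch the occluded forwards
  chunk <- 64L
  pos <- expand.grid(i = seq_along(offs), j = seq_along(offs))
  at <- 1L
  while (at <= npos) {
    take <- at:min(at + chunk - 1L, npos)
    xb <- array(rep(x, length(take)), c(n, n, 1L, length(take)))
    for (q in seq_along(take)) {
      r0 <- offs[pos$i[take[q]]]; c0 <- offs[pos$j[take[q]]]
      xb[r0 + seq_len(S), c0 + seq_len(S), 1L, q] <- 0
    }
    pr <- nn_predict_probs(model$net, xb)
    vals[cbind(pos$i[take], pos$j[take])] <- p0[ti] - pr[ti, ]
    at <- at + length(take)
  }
  structure(list(values = vals, row_offsets = offs, col_offsets = offs,
                 occluder_size = S,
                 occluder_stride = as.integer(occluder_stride),
                 target_class = target_class, p_original = p0[ti]),
            class = "attention_map")
}

#' @export
print.attention_map <- function(x, ...) {
  cat(sprintf(paste0("<attention_map> %dx%d positions (occluder %d, stride ",
                     "%d), target class %d, max drop %.3f\n"),
              nrow(x$values), ncol(x$values), x$occluder_size,
              x$occluder_stride, x$target_class, max(x$values)))
  invisible(x)
}

#' @export
plot.attention_map <- function(x, ...) {
  image(t(x$values)[, rev(seq_len(nrow(x$values)))],
        col = hcl.colors(64, "inferno"), axes = FALSE,
        main = sprintf("occlusion attention (class %d)", x$target_class), ...)
  invisible(x)
}

#' Skeletal maturity stage for a bone age
#'
#' Lower-inclusive half-open bins: females prepuberty `[0, 7)`,
#' early-and-mid puberty `[7, 13)`, late puberty `[13, 15)`, postpuberty
#' `[15, Inf)`; males `[0, 9)`, `[9, 14)`, `[14, 17)`, `[17, Inf)`.
#'
#' @param sex `"female"` or `"male"` (vectorized).
#' @param bone_age_years non-negative real (vectorized).
#' @return factor over prepuberty, early_mid_puberty, late_puberty,
#'   postpuberty.
#' @export
maturity_stage <- function(sex, bone_age_years) {
  if (any(bone_age_years < 0))
    baa_stop("baa_domain_error", "bone age must be non-negative")
  sex <- match.arg(sex, c("female", "male"), several.ok = TRUE)
  n <- max(length(sex), length(bone_age_years))
  sex <- rep_len(sex, n); age <- rep_len(bone_age_years, n)
  cuts <- list(female = c(7, 13, 15), male = c(9, 14, 17))
  lev <- c("prepuberty", "early_mid_puberty", "late_puberty", "postpuberty")
  stage <- vapply(seq_len(n), function(i) {
    1L + sum(age[i] >= cuts[[sex[i]]])
  }, integer(1))
  factor(lev[stage], levels = lev)
}

#' Fraction of positive attention mass on growth-plate regions
#'
#' Utility for judging whether a phantom-trained classifier attends to
#' the age-discriminative growth-plate gaps: sums the positive values of
#' an attention map over occluder positions whose (input-scale) square
#' overlaps any ground-truth gap rectangle and divides by the total
#' positive mass.
#'
#' @param amap an [occlusion_map()] result.
#' @param gap_boxes data frame of gap rectangles in the coordinates of
#'   the image the map was computed on (1-based inclusive
#'   `r0, r1, c0, c1`); use the normalized truth scaled to the
#'   classifier input size.
#' @param scale factor mapping the gap-box coordinates to the attention
#'   input scale (e.g. 224/512 for boxes at the working resolution).
#' @return proportion in `[0, 1]` (`NaN` when there is no positive mass).
#' @export
attention_on_gaps <- function(amap, gap_boxes, scale = 1) {
  stopifnot(inherits(amap, "attention_map"))
  v <- pmax(amap$values, 0)
  total <- sum(v)
  S <- amap$occluder_size
  hit <- matrix(FALSE, nrow(v), ncol(v))
  for (q in seq_len(nrow(gap_boxes))) {
    b <- gap_boxes[q, ]
    r0 <- (b$r0 - 1) * scale; r1 <- b$r1 * scale
    c0 <- (b$c0 - 1) * scale; c1 <- b$c1 * scale
    hit <- hit | outer(amap$row_offsets, amap$col_offsets,
                       function(ro, co) ro < r1 & (ro + S) > r0 &
                         co < c1 & (co + S) > c0)
  }
  sum(v[hit]) / total
}
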