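# Bone-age classification: inception-style backbone, layer-wise
# fine-tuning depth control, SGD training with the 9-combination
# hyperparameter grid, per-image prediction over the 14 age classes.

BAA_GROUP_ORDER <- c("conv1", "conv2", "inception4", "inception5", "fc")

# Inception-style backbone over 224x224x1 inputs. The "small" preset is a
# reduced-width network (two inception blocks) trainable on a CPU in
# minutes; "full" approaches the width of the classic 22-layer topology
# and is available behind this flag for larger runs.
backbone_layers <- function(backbone = c("small", "full")) {
  backbone <- match.arg(backbone)
  if (backbone == "small") {
    w <- c(c1 = 8, c2 = 16, i4a = 8, i4r = 8, i4b = 16,
           i5a = 12, i5r = 8, i5b = 20, fc = 48)
  } else {
    w <- c(c1 = 64, c2 = 128, i4a = 64, i4r = 48, i4b = 96,
           i5a = 96, i5r = 64, i5b = 128, fc = 256)
  }
  list(nn_conv(7, 2, 3, 1, w[["c1"]], "conv1", bn = TRUE),    # 224 -> 112
       nn_pool(),                                            # -> 56
       nn_conv(3, 1, 1, w[["c1"]], w[["c2"]], "conv2", bn = TRUE),
       nn_pool(),                                            # -> 28
       nn_inception("inception4", w[["c2"]], w[["i4a"]], w[["i4r"]],
                    w[["i4b"]], bn = TRUE),
       nn_pool(),                                            # -> 14
       nn_inception("inception5", w[["i4a"]] + w[["i4b"]],
                    w[["i5a"]], w[["i5r"]], w[["i5b"]], bn = TRUE),
       nn_pool(),                                            # -> 7
       nn_flatten(),
       nn_fc(7L * 7L * (w[["i5a"]] + w[["i5b"]]), w[["fc"]], "fc",
             relu = TRUE),
       nn_fc(w[["fc"]], 14L, "fc"))
}

#' Collapse RGB first-layer filters to one grayscale channel
#'
#' Pretrained networks for natural images have three-channel first-layer
#' filters; radiographs are single-channel. Each output tap becomes the
#' arithmetic mean of its three channel taps; filter count and spatial
#' extent are unchanged.
#'
#' @param rgb_first_layer numeric array `k x k x 3 x n_filters`.
#' @return array `k x k x 1 x n_filters`.
#' @export
convert_filters_grayscale <- function(rgb_first_layer) {
  d <- dim(rgb_first_layer)
  if (length(d) != 4L || d[3] != 3L)
    baa_stop("baa_shape_error", "expected a k x k x 3 x n filter bank")
  out <- (rgb_first_layer[, , 1L, , drop = FALSE] +
            rgb_first_layer[, , 2L, , drop = FALSE] +
            rgb_first_layer[, , 3L, , drop = FALSE]) / 3
  out
}

#' Training configuration for the bone-age classifier
#'
#' Defaults follow the classification stage's training recipe: SGD with
#' momentum 0.9, weight decay 0.005, mini-batch size 96, 100 epochs, the
#' learning rate multiplied by `gamma` at three evenly spaced epoch
#' boundaries. For grid-search runs `base_lr` ranges over
#' `{0.001, 0.005, 0.01}` and `gamma` over `{0.1, 0.5, 0.75}`.
#'
#' @param base_lr base learning rate.
#' @param gamma learning-rate decay factor applied at each step.
#' @param momentum SGD momentum.
#' @param weight_decay L2 weight decay.
#' @param batch_size mini-batch size.
#' @param epochs training epochs.
#' @param finetune_depth `"scratch"`, `"all"`, or the earliest layer group
#'   to unfreeze (`"fc"`, `"inception5"`, `"inception4"`, `"conv2"`,
#'   `"conv1"`).
#' @param augmentation an [default_augmentation_config()] or `NULL` to
#'   disable on-the-fly augmentation.
#' @param backbone `"small"` (desk-scale reduced-width network) or
#'   `"full"`.
#' @param validation_fraction per-class fraction held out when no
#'   explicit validation set is supplied.
#' @param seed integer seed.
#' @return an object of class `baa_train_config`.
#' @export
train_config <- function(base_lr = 0.005, gamma = 0.5, momentum = 0.9,
                         weight_decay = 0.005, batch_size = 96L,
                         epochs = 100L, finetune_depth = "scratch",
                         augmentation = NULL, backbone = "small",
                         validation_fraction = 0.25, seed = 1L) {
  if (!finetune_depth %in% c("scratch", "all", BAA_GROUP_ORDER))
    baa_stop("baa_config_error",
             sprintf("unknown finetune depth '%s'", finetune_depth))
  structure(list(base_lr = base_lr, gamma = gamma, momentum = momentum,
                 weight_decay = weight_decay, batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs), finetune_depth = finetune_depth,
                 augmentation = augmentation, backbone = backbone,
                 validation_fraction = validation_fraction,
                 seed = as.integer(seed)),
            class = "baa_train_config")
}

#' Set the layer-wise fine-tuning depth of a classifier
#'
#' Marks the named layer group and all later groups trainable and
#' freezes the earlier ones, following the incremental last-to-first
#' fine-tuning schema. `"all"` unfreezes everything (fine-tune every
#' layer from its current initialization); `"scratch"` unfreezes
#' everything and re-randomizes all parameters.
#'
#' @param model a `baa_classifier`.
#' @param depth one of `"scratch"`, `"all"`, `"fc"`, `"inception5"`,
#'   `"inception4"`, `"conv2"`, `"conv1"`.
#' @param seed seed for the re-randomization of `"scratch"`.
#' @return the model with updated frozen groups.
#' @export
set_finetune_depth <- function(model, depth, seed = 1L) {
  stopifnot(inherits(model, "baa_classifier"))
  if (!depth %in% c("scratch", "all", BAA_GROUP_ORDER))
    baa_stop("baa_config_error", sprintf("unknown layer group '%s'", depth))
  if (depth == "scratch") {
    model$net <- with_seed(seed, nn_build(backbone_layers(model$backbone),
                                          c(224L, 224L, 1L), 14L))
    model$net$frozen <- character(0)
    model$pretrained <- FALSE
  } else if (depth == "all") {
    model$net$frozen <- character(0)
  } else {
    if (!model$pretrained)
      baa_warn("baa_no_pretrained",
               paste("no pretrained parameters loaded; freezing",
                     "randomly initialized layers"))
    keep <- BAA_GROUP_ORDER[seq_len(match(depth, BAA_GROUP_ORDER) - 1L)]
    model$net$frozen <- keep
  }
  model$finetune_depth <- depth
  model
}

#' Frozen / trainable layer groups of a classifier
#' @param model a `baa_classifier`.
#' @return list with `frozen` and `trainable` group name vectors.
#' @export
finetune_groups <- function(model) {
  stopifnot(inherits(model, "baa_classifier"))
  list(frozen = model$net$frozen,
       trainable = setdiff(BAA_GROUP_ORDER, model$net$frozen))
}

#' Build an untrained bone-age classifier
#'
#' @param sex cohort the model is for (models are trained per sex).
#' @param backbone `"small"` or `"full"`.
#' @param pretrained optional list of parameters to initialize from (a
#'   previously trained `baa_classifier`'s `net$layers`); when absent the
#'   network starts from random initialization and fine-tune depths fall
#'   back to scratch behaviour with a warning.
#' @param seed seed for random initialization.
#' @return an object of class `baa_classifier`.
#' @export
baa_classifier <- function(sex = c("female", "male"), backbone = "small",
                           pretrained = NULL, seed = 1L) {
  sex <- match.arg(sex)
  net <- with_seed(seed, nn_build(backbone_layers(backbone),
                                  c(224L, 224L, 1L), 14L))
  has_pre <- !is.null(pretrained)
  if (has_pre) net$layers <- pretrained
  structure(list(net = net, sex = sex, backbone = backbone,
                 classes = BAA_AGE_CLASSES, pretrained = has_pre,
                 finetune_depth = if (has_pre) "all" else "scratch",
                 history = NULL),
            class = "baa_classifier")
}

#' @export
print.baa_classifier <- function(x, ...) {
  fg <- finetune_groups(x)
  cat(sprintf(paste0("<baa_classifier> %s cohort, %s backbone, 14 classes ",
                     "(5-18 y)\n  depth=%s; trainable: %s%s\n"),
              x$sex, x$backbone, x$finetune_depth,
              paste(fg$trainable, collapse = ", "),
              if (!is.null(x$history))
                sprintf("; best val accuracy %.3f",
                        max(x$history$val_accuracy)) else ""))
  invisible(x)
}

# Down-sample a preprocessed radiograph (or [0,1] matrix) to the
# network's 224x224 input by exact area averaging.
classifier_input <- function(image, target = 224L) {
  if (inherits(image, "radiograph")) {
    m <- image$pixels / max_intensity(image$bit_depth)
  } else m <- image
  if (nrow(m) != ncol(m))
    baa_stop("baa_shape_error", "classifier input must be square (preprocess first)")
  if (nrow(m) != target) m <- area_downsample(m, target)
  m
}

images_to_batch <- function(images, target = 224L) {
  n <- length(images)
  x <- array(0, c(target, target, 1L, n))
  for (i in seq_len(n)) x[, , 1L, i] <- classifier_input(images[[i]], target)
  x
}

#' Train the bone-age classifier
#'
#' @param images list of preprocessed [radiograph()]s (512x512, output of
#'   the preprocessing engine) or `[0,1]` matrices; radiographs must
#'   carry `bone_age_label` when `labels` is missing.
#' @param cfg a [train_config()].
#' @param labels optional integer bone-age labels in 5..18.
#' @param validation optional `list(images =, labels =)` used for
#'   best-model selection; when absent, `cfg$validation_fraction` per
#'   class is held out.
#' @param model optional starting [baa_classifier()] (e.g. carrying
#'   pretrained parameters and a fine-tune depth); built fresh per `cfg`
#'   otherwise.
#' @param sex cohort label when building a fresh model.
#' @return the trained `baa_classifier`: `$net` holds the
#'   best-by-validation-accuracy epoch snapshot used for prediction,
#'   `$final_net` the last-epoch state (useful for judging how well the
#'   optimizer fit its training data), and `$history` the per-epoch
#'   training log (`epoch`, `loss`, `val_accuracy`).
#' @export
train_bone_age_classifier <- function(images, cfg = train_config(),
                                      labels = NULL, validation = NULL,
                                      model = NULL, sex = "female") {
  stopifnot(inherits(cfg, "baa_train_config"))
  if (is.null(labels))
    labels <- vapply(images, function(r) r$bone_age_label, integer(1))
  if (any(!labels %in% 5:18))
    baa_stop("baa_out_of_cohort", "labels must lie in [5, 18]")
  y <- match(labels, BAA_AGE_CLASSES)
  if (is.null(model)) {
    model <- baa_classifier(sex = sex, backbone = cfg$backbone,
                            seed = cfg$seed)
    model <- set_finetune_depth(model, cfg$finetune_depth, seed = cfg$seed)
  }
  x <- images_to_batch(images)
  holdout <- integer(0)
  if (is.null(validation)) {
    holdout <- with_seed(cfg$seed + 17L, unlist(lapply(unique(y), function(cl) {
      idx <- which(y == cl)
      sample(idx, max(1L, round(cfg$validation_fraction * length(idx))))
    })))
    tr <- setdiff(seq_along(y), holdout)
    vx <- x[, , , holdout, drop = FALSE]; vy <- y[holdout]
    x <- x[, , , tr, drop = FALSE]; y <- y[tr]
  } else {
    vx <- images_to_batch(validation$images)
    vy <- match(validation$labels, BAA_AGE_CLASSES)
  }
  aug_fn <- if (!is.null(cfg$augmentation)) augmentation_stream(cfg$augmentation)
  fit <- nn_train(model$net, x, y, vx, vy, epochs = cfg$epochs,
                  base_lr = cfg$base_lr, gamma = cfg$gamma,
                  momentum = cfg$momentum, weight_decay = cfg$weight_decay,
                  batch_size = cfg$batch_size, seed = cfg$seed + 31L,
                  augment_fn = aug_fn)
  model$net <- fit$net            # best-by-validation snapshot
  model$final_net <- fit$final_net  # last-epoch state (fit diagnostics)
  model$history <- fit$history
  model$best_epoch <- fit$best_epoch
  model$holdout <- holdout        # indices held out of `images` internally
  model$config <- cfg
  model
}

#' Grid search over base learning rates and gamma values
#'
#' One training run per `(base_lr, gamma)` pair (the default grids give
#' the 9-combination search); the winner is the run with the highest
#' validation accuracy. The full result table is retained.
#'
#' @param images,labels,validation,sex as in [train_bone_age_classifier()].
#' @param lrs base learning-rate grid.
#' @param gammas gamma grid.
#' @param fixed a [train_config()] supplying all other fields.
#' @return list with `model` (best classifier), `best` (winning config)
#'   and `results` (data frame lr / gamma / val_accuracy).
#' @export
grid_search_bone_age <- function(images, lrs = c(0.001, 0.005, 0.01),
                                 gammas = c(0.1, 0.5, 0.75),
                                 fixed = train_config(), labels = NULL,
                                 validation = NULL, sex = "female") {
  stopifnot(length(lrs) >= 1L, length(gammas) >= 1L)
  results <- data.frame()
  best <- NULL; best_acc <- -Inf; failures <- 0L
  for (lr in lrs) for (g in gammas) {
    cfg <- fixed
    cfg$base_lr <- lr; cfg$gamma <- g
    m <- tryCatch(
      train_bone_age_classifier(images, cfg, labels = labels,
                                validation = validation, sex = sex),
      baa_training_failure = function(e) NULL)
    acc <- if (is.null(m)) NA_real_ else max(m$history$val_accuracy)
    results <- rbind(results,
                     data.frame(base_lr = lr, gamma = g, val_accuracy = acc))
    if (is.null(m)) failures <- failures + 1L
    else if (acc > best_acc) {
      best_acc <- acc
      best <- list(model = m, config = cfg)
    }
  }
  if (is.null(best))
    baa_stop("baa_grid_failure", "all grid-search runs failed to converge")
  list(model = best$model, best = best$config, results = results)
}

#' Predict a bone age for one preprocessed radiograph
#'
#' Deterministic: the same image always yields the same assessment.
#'
#' @param object a trained `baa_classifier`.
#' @param image preprocessed [radiograph()] (square) or `[0,1]` matrix.
#' @param topk number of ranked suggestions to return (default 5).
#' @param ... unused.
#' @return an object of class `bone_age_prediction`: `probabilities`
#'   (named 14-vector summing to 1), `top1` (integer years), `topk`
#'   (data frame of class / probability, descending).
#' @export
predict.baa_classifier <- function(object, image, topk = 5L, ...) {
  x <- classifier_input(image)
  p <- as.numeric(nn_predict_probs(object$net, array(x, c(dim(x), 1L, 1L))))
  names(p) <- as.character(BAA_AGE_CLASSES)
  ord <- order(p, decreasing = TRUE)
  k <- min(topk, length(p))
  structure(list(probabilities = p,
                 top1 = BAA_AGE_CLASSES[ord[1L]],
                 topk = data.frame(bone_age = BAA_AGE_CLASSES[ord[seq_len(k)]],
                                   probability = p[ord[seq_len(k)]],
                                   row.names = NULL),
                 sex = object$sex),
            class = "bone_age_prediction")
}

#' @export
print.bone_age_prediction <- function(x, ...) {
  cat(sprintf("<bone_age_prediction> %d years (p=%.3f, %s cohort)\n",
              x$top1, max(x$probabilities), x$sex))
  invisible(x)
}
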