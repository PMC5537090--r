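#' Sample a balanced, labelled patch dataset from normalized phantoms
#'
#' Draws exactly `n_per_class` square patches for each of the five pixel
#' classes from a corpus of normalized images with ground truth. A patch's
#' label is the ground-truth class of its center pixel; patches always lie
#' fully inside their source image. Candidate centers are drawn without
#' replacement until a class is exhausted, then with replacement.
#'
#' @param images list of `list(radiograph, truth)` pairs at the working
#'   resolution (see [normalize_phantom()]).
#' @param n_per_class patches per class.
#' @param patch_size square patch side `S`; the center pixel is at offset
#'   `floor(S/2)` (0-based) from the patch's top-left corner.
#' @param seed integer seed; sampling is deterministic given it.
#' @return an object of class `patch_dataset`: `patches` (`S x S x N`
#'   array of intensities normalized to `[0, 1]`), `labels` (integer
#'   1..5 over bone, tissue, background, collimation, annotation),
#'   `patch_size`, `seed`.
#' @export
sample_patches <- function(images, n_per_class, patch_size = 32L, seed = 1L) {
  stopifnot(length(images) >= 1L, n_per_class >= 1L, patch_size >= 2L)
  S <- as.integer(patch_size)
  off <- S %/% 2L  # center offset from top-left (0-based)
  # candidate centers per class across the corpus
  cands <- vector("list", 5L)
  for (ii in seq_along(images)) {
    cm <- images[[ii]]$truth$class_map
    h <- nrow(cm); w <- ncol(cm)
    if (S > h || S > w)
      baa_stop("baa_geometry_error", "patch larger than image")
    rlo <- 1L + off; rhi <- h - (S - 1L - off)
    clo <- 1L + off; chi <- w - (S - 1L - off)
    sub <- cm[rlo:rhi, clo:chi, drop = FALSE]
    for (cl in 1:5) {
      hit <- which(sub == cl)
      if (length(hit)) {
        r <- ((hit - 1L) %% nrow(sub)) + rlo
        c <- ((hit - 1L) %/% nrow(sub)) + clo
        cands[[cl]] <- rbind(cands[[cl]], cbind(ii, r, c))
      }
    }
  }
  missing <- which(vapply(cands, is.null, TRUE))
  if (length(missing))
    baa_stop("baa_missing_class",
             sprintf("no pixels of class %s in the corpus",
                     paste(BAA_CLASSES[missing], collapse = ", ")))
  patches <- array(0, c(S, S, 5L * n_per_class))
  labels <- integer(5L * n_per_class)
  with_seed(seed, {
    at <- 0L
    for (cl in 1:5) {
      pool <- cands[[cl]]
      npool <- nrow(pool)
      take <- if (n_per_class <= npool) {
        pool[sample.int(npool, n_per_class), , drop = FALSE]
      } else {
        rbind(pool[sample.int(npool), , drop = FALSE],
              pool[sample.int(npool, n_per_class - npool, replace = TRUE), ,
                   drop = FALSE])
      }
      for (q in seq_len(n_per_class)) {
        ii <- take[q, 1L]
        r0 <- take[q, 2L] - off
        c0 <- take[q, 3L] - off
        rg <- images[[ii]]$radiograph
        patches[, , at + q] <-
          rg$pixels[r0:(r0 + S - 1L), c0:(c0 + S - 1L)] /
          max_intensity(rg$bit_depth)
        labels[at + q] <- cl
      }
      at <- at + n_per_class
    }
  })
  structure(list(patches = patches, labels = labels, patch_size = S,
                 seed = as.integer(seed)), class = "patch_dataset")
}

#' @export
print.patch_dataset <- function(x, ...) {
  cat(sprintf("<patch_dataset> %d patches of %dx%d (%d per class)\n",
              length(x$labels), x$patch_size, x$patch_size,
              length(x$labels) %/% 5L))
  invisible(x)
}

# LeNet-5-style topology: two conv+pool blocks and two fully connected
# layers over 5 outputs. Patch sizes must be multiples of 4 so both
# pooling stages see even extents.
lenet_layers <- function(patch_size) {
  S <- as.integer(patch_size)
  if (S %% 4L != 0L || S < 12L)
    baa_stop("baa_geometry_error",
             "patch size must be a multiple of 4 and at least 12")
  a <- ((S - 4L) %/% 2L - 4L) %/% 2L
  list(nn_conv(5, 1, 0, 1, 6, "conv1"),
       nn_pool(),
       nn_conv(5, 1, 0, 6, 16, "conv2"),
       nn_pool(),
       nn_flatten(),
       nn_fc(16L * a * a, 120L, "fc", relu = TRUE),
       nn_fc(120L, 5L, "fc"))
}

#' Train the five-class patch detection network
#'
#' A LeNet-5-style CNN (two conv+pool blocks, two fully connected layers,
#' softmax over the five pixel classes) trained with SGD: base learning
#' rate 0.01 decreased by a factor of ten at three evenly spaced epoch
#' boundaries, momentum 0.9. 25% of the patches per class are held out as
#' a validation set and the best-by-validation-accuracy epoch snapshot is
#' returned.
#'
#' @param data a [sample_patches()] result (at least 10 patches per class).
#' @param epochs training epochs (default 100).
#' @param base_lr base learning rate (default 0.01).
#' @param batch_size mini-batch size.
#' @param seed integer seed for holdout, shuffling and initialization.
#' @return an object of class `patch_classifier` with the trained network,
#'   the per-epoch history, `patch_size` and `validation_accuracy`.
#' @export
train_patch_classifier <- function(data, epochs = 100L, base_lr = 0.01,
                                   batch_size = 64L, seed = 1L) {
  stopifnot(inherits(data, "patch_dataset"))
  n <- length(data$labels)
  if (min(tabulate(data$labels, 5L)) < 10L)
    baa_stop("baa_insufficient_data", "need at least 10 patches per class")
  hold <- with_seed(seed + 1L, {
    unlist(lapply(1:5, function(cl) {
      idx <- which(data$labels == cl)
      sample(idx, round(0.25 * length(idx)))
    }))
  })
  tr <- setdiff(seq_len(n), hold)
  S <- data$patch_size
  to4d <- function(idx) {
    x <- data$patches[, , idx, drop = FALSE]
    dim(x) <- c(S, S, 1L, length(idx))
    x
  }
  net <- with_seed(seed, nn_build(lenet_layers(S), c(S, S, 1L), 5L))
  fit <- nn_train(net, to4d(tr), data$labels[tr], to4d(hold), data$labels[hold],
                  epochs = epochs, base_lr = base_lr, gamma = 0.1,
                  momentum = 0.9, weight_decay = 0.0005,
                  batch_size = batch_size, seed = seed + 2L)
  structure(list(net = fit$net, patch_size = S, classes = BAA_CLASSES,
                 history = fit$history, best_epoch = fit$best_epoch,
                 validation_accuracy = fit$best_val_accuracy,
                 n_train = length(tr), n_validation = length(hold)),
            class = "patch_classifier")
}

#' @export
print.patch_classifier <- function(x, ...) {
  cat(sprintf(paste0("<patch_classifier> LeNet-5-style, %dx%d patches, ",
                     "val accuracy %.3f (epoch %d; %d train / %d holdout)\n"),
              x$patch_size, x$patch_size, x$validation_accuracy,
              x$best_epoch, x$n_train, x$n_validation))
  invisible(x)
}

#' Score a single patch with the detection network
#'
#' @param model a [train_patch_classifier()] result.
#' @param patch `S x S` intensity grid. Values above 1 are assumed to be
#'   raw intensities and are rescaled by `maxval`.
#' @param maxval dynamic-range maximum used for rescaling raw patches
#'   (default 255).
#' @return numeric 5-vector of softmax class scores (non-negative, sums
#'   to 1) named by class.
#' @export
score_patch <- function(model, patch, maxval = 255) {
  stopifnot(inherits(model, "patch_classifier"))
  if (!is.matrix(patch) || nrow(patch) != model$patch_size ||
      ncol(patch) != model$patch_size)
    baa_stop("baa_shape_error",
             sprintf("patch must be %dx%d", model$patch_size, model$patch_size))
  if (max(patch) > 1) patch <- patch / maxval
  x <- array(patch, c(dim(patch), 1L, 1L))
  p <- as.numeric(nn_predict_probs(model$net, x))
  names(p) <- model$classes
  p
}

# batched scoring used by the sliding-window reconstruction
score_patch_array <- function(model, x4d, chunk = 2048L) {
  t(nn_predict_probs(model$net, x4d, chunk = chunk))
}

# Score every grid-aligned patch position of a whole [0,1] image.
# Returns a (nr*nc) x 5 matrix of softmax scores, positions in
# column-major order over the (row, col) offset grid.
#
# When the stride is a multiple of 4 (the product of the two 2x pooling
# stages) and the image extents are even, all patch windows align with a
# single full-image pass: conv1/pool/conv2/pool run once over the whole
# image and the fully connected layers act as convolutions over the
# pooled feature map. This is exactly equivalent to scoring each patch
# independently; otherwise the generic patch-batch path is used.
score_grid <- function(model, x01, patch_size, stride) {
  H <- nrow(x01); W <- ncol(x01)
  S <- patch_size
  nr <- (H - S) %/% stride + 1L
  nc <- (W - S) %/% stride + 1L
  fast <- stride %% 4L == 0L && S %% 4L == 0L && H %% 2L == 0L &&
    W %% 2L == 0L && S >= 12L
  if (fast) {
    lay <- model$net$layers
    x <- array(x01, c(H, W, 1L, 1L))
    x <- conv_fwd(lay[[1]], x, keep = FALSE)$out
    d <- dim(x); x <- maxpool2(x, d[1], d[2], d[3], d[4])
    x <- conv_fwd(lay[[3]], x, keep = FALSE)$out
    d <- dim(x); x <- maxpool2(x, d[1], d[2], d[3], d[4])
    a <- (S - 12L) %/% 4L   # fc window in the twice-pooled map
    fc1 <- lay[[6]]; fc2 <- lay[[7]]
    cfc1 <- list(type = "conv", k = a, stride = stride %/% 4L, pad = 0L,
                 cin = 16L, cout = ncol(fc1$W), relu = fc1$relu,
                 W = fc1$W, b = fc1$b, group = "fc")
    x <- conv_fwd(cfc1, x, keep = FALSE)$out
    cfc2 <- list(type = "conv", k = 1L, stride = 1L, pad = 0L, cin = ncol(fc1$W),
                 cout = 5L, relu = FALSE, W = fc2$W, b = fc2$b, group = "fc")
    x <- conv_fwd(cfc2, x, keep = FALSE)$out
    stopifnot(dim(x)[1] == nr, dim(x)[2] == nc)
    logits <- matrix(x, nr * nc, 5L)
    t(softmax_cols(t(logits)))
  } else {
    X <- im2col_batch(as.numeric(x01), H, W, 1L, 1L, S, as.integer(stride), 0L)
    x4d <- array(t(X), c(S, S, 1L, nr * nc))
    score_patch_array(model, x4d)
  }
}
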