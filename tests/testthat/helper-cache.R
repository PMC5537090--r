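# Shared fixtures built once per test run. Trained models and phantom
# corpora are cached in this environment so the segmentation, attention
# and pipeline tests reuse the same objects instead of retraining.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- build()
  .fixtures[[name]]
}

# small, quick phantoms for unit tests (the acceptance suite uses the
# full-size defaults)
tiny_cohort <- function(n_per_class, seed, classes = 5:18,
                        sexes = c("female", "male")) {
  generate_cohort(n_per_class, sexes = sexes, seed = seed, classes = classes,
                  size_range = c(96L, 160L))
}

# the shared patch detector used by segmentation-level tests and the
# acceptance suite (trained at the working scale: 32x32 patches)
shared_detector <- function() {
  fixture("detector", function() {
    train_n <- lapply(generate_cohort(1, seed = 11), normalize_phantom)
    ds <- sample_patches(train_n, 1000, 32, seed = 3)
    train_patch_classifier(ds, epochs = 25, batch_size = 32, seed = 4)
  })
}

shared_test_phantoms <- function() {
  fixture("test_phantoms", function() {
    lapply(generate_cohort(1, seed = 99,
                           classes = c(5, 7, 9, 11, 13, 15, 17, 18, 6, 10)),
           normalize_phantom)[1:20]
  })
}

# detector trained on constant-intensity patches: the five classes are
# trivially separable, so this doubles as the convergence smoke test
separable_patch_data <- function(n_per_class = 500, seed = 2) {
  S <- 32L
  levels <- c(bone = 0.8, tissue = 0.35, background = 0.05,
              collimation = 0.2, annotation = 0.95)
  x <- array(0, c(S, S, 5L * n_per_class))
  y <- integer(5L * n_per_class)
  set.seed(seed)
  for (cl in 1:5) for (q in seq_len(n_per_class)) {
    i <- (cl - 1L) * n_per_class + q
    x[, , i] <- levels[cl] + matrix(rnorm(S * S, sd = 0.02), S, S)
    y[i] <- cl
  }
  structure(list(patches = x, labels = y, patch_size = S, seed = seed),
            class = "patch_dataset")
}

shared_separable_detector <- function() {
  fixture("sep_detector", function() {
    train_patch_classifier(separable_patch_data(), epochs = 5,
                           batch_size = 16, seed = 1)
  })
}

# Preprocessed classifier corpus: 6 bone-age classes x 20 phantoms,
# normalized, segmented with the ground-truth masks and standardized by
# the vision pipeline.
CLS_CLASSES <- 5:10

shared_classifier_data <- function() {
  fixture("cls_data", function() {
    coh <- generate_cohort(20, sexes = "female", seed = 21,
                           classes = CLS_CLASSES,
                           size_range = c(512L, 900L))
    pre <- lapply(coh, function(ph) {
      n <- normalize_phantom(ph)
      img <- vision_pipeline(n$radiograph, n$truth$hand_mask)
      attr(img, "gap_boxes") <- n$truth$gap_boxes
      img
    })
    list(images = pre,
         labels = vapply(pre, function(r) r$bone_age_label, integer(1)))
  })
}

shared_heldout_data <- function() {
  fixture("cls_heldout", function() {
    coh <- generate_cohort(3, sexes = "female", seed = 77,
                           classes = CLS_CLASSES,
                           size_range = c(512L, 900L))
    pre <- lapply(coh, function(ph) {
      n <- normalize_phantom(ph)
      img <- vision_pipeline(n$radiograph, n$truth$hand_mask)
      attr(img, "gap_boxes") <- n$truth$gap_boxes
      attr(img, "norm_truth") <- n$truth
      img
    })
    list(images = pre,
         labels = vapply(pre, function(r) r$bone_age_label, integer(1)))
  })
}

# Desk-scale bone-age classifier trained from scratch on the shared
# corpus; reused by the classification, attention and pipeline tests.
shared_classifier <- function() {
  fixture("classifier", function() {
    d <- shared_classifier_data()
    cfg <- train_config(epochs = 160, base_lr = 0.03, gamma = 0.5,
                        batch_size = 12, seed = 7,
                        finetune_depth = "scratch", augmentation = NULL,
                        validation_fraction = 0.15)
    train_bone_age_classifier(d$images, cfg, sex = "female")
  })
}
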