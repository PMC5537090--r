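test_that("RGB filter banks collapse to grayscale by channel means", {
  # identical channels stay put
  bank <- array(0.4, c(5, 5, 3, 2))
  out <- convert_filters_grayscale(bank)
  expect_identical(dim(out), c(5L, 5L, 1L, 2L))
  expect_equal(max(abs(out - 0.4)), 0, tolerance = 1e-12)
  # (0.3, 0.6, 0.9) -> 0.6
  bank2 <- array(0, c(1, 1, 3, 1))
  bank2[1, 1, , 1] <- c(0.3, 0.6, 0.9)
  expect_equal(as.numeric(convert_filters_grayscale(bank2)), 0.6)
  # 64 filters of 7x7x3 against an independent per-tap mean
  set.seed(12)
  big <- array(rnorm(7 * 7 * 3 * 64), c(7, 7, 3, 64))
  conv <- convert_filters_grayscale(big)
  oracle <- apply(big, c(1, 2, 4), mean)
  expect_equal(conv[, , 1, ], oracle, tolerance = 1e-12)
  expect_error(convert_filters_grayscale(array(0, c(3, 3, 4, 2))),
               class = "baa_shape_error")
})

test_that("training configuration defaults follow the published recipe", {
  cfg <- train_config()
  expect_identical(cfg$momentum, 0.9)
  expect_identical(cfg$weight_decay, 0.005)
  expect_identical(cfg$batch_size, 96L)
  expect_identical(cfg$epochs, 100L)
  expect_error(train_config(finetune_depth = "conv9"),
               class = "baa_config_error")
})

test_that("fine-tuning depth freezes exactly the earlier layer groups", {
  m <- baa_classifier("female", seed = 2)
  m$pretrained <- TRUE   # pretend parameters were loaded
  m_fc <- set_finetune_depth(m, "fc")
  expect_setequal(finetune_groups(m_fc)$trainable, "fc")
  expect_setequal(finetune_groups(m_fc)$frozen,
                  c("conv1", "conv2", "inception4", "inception5"))
  m_i5 <- set_finetune_depth(m, "inception5")
  expect_setequal(finetune_groups(m_i5)$trainable, c("inception5", "fc"))
  expect_true("conv1" %in% finetune_groups(m_i5)$frozen)
  m_all <- set_finetune_depth(m, "all")
  expect_length(finetune_groups(m_all)$frozen, 0)
  expect_error(set_finetune_depth(m, "pool7"), class = "baa_config_error")
  # scratch re-randomizes
  m_s <- set_finetune_depth(m, "scratch", seed = 99)
  expect_false(identical(m_s$net$layers[[1]]$W, m$net$layers[[1]]$W))
  # without pretrained parameters, freezing warns
  m2 <- baa_classifier("female", seed = 2)
  expect_warning(set_finetune_depth(m2, "fc"), class = "baa_no_pretrained")
})

test_that("frozen layer groups stay bit-identical through training", {
  ab <- asNamespace("autobaa")
  imgs <- replicate(8, matrix(runif(224 * 224, 0, 0.9), 224, 224),
                    simplify = FALSE)
  labels <- rep(c(6L, 12L), 4)
  model <- baa_classifier("female", seed = 5)
  model$pretrained <- TRUE
  model <- set_finetune_depth(model, "inception5")
  before <- lapply(c("conv1", "conv2", "inception4", "inception5", "fc"),
                   function(g) ab$nn_group_params(model$net, g))
  cfg <- train_config(epochs = 2, base_lr = 0.01, batch_size = 4, seed = 3)
  fit <- train_bone_age_classifier(imgs, cfg, labels = labels,
                                   validation = list(images = imgs,
                                                     labels = labels),
                                   model = model)
  after <- lapply(c("conv1", "conv2", "inception4", "inception5", "fc"),
                  function(g) ab$nn_group_params(fit$net, g))
  expect_identical(before[[1]], after[[1]])   # conv1 frozen
  expect_identical(before[[2]], after[[2]])   # conv2 frozen
  expect_identical(before[[3]], after[[3]])   # inception4 frozen
  expect_false(identical(before[[4]], after[[4]]))  # inception5 trains
  expect_false(identical(before[[5]], after[[5]]))  # fc trains
})

test_that("the hyperparameter grid search runs one fit per combination", {
  imgs <- replicate(6, matrix(runif(224 * 224, 0, 0.9), 224, 224),
                    simplify = FALSE)
  labels <- rep(c(6L, 12L, 16L), 2)
  fixed <- train_config(epochs = 1, batch_size = 3, seed = 2)
  gs <- grid_search_bone_age(imgs, fixed = fixed, labels = labels,
                             validation = list(images = imgs, labels = labels))
  expect_identical(nrow(gs$results), 9L)   # 3 learning rates x 3 gammas
  expect_setequal(unique(gs$results$base_lr), c(0.001, 0.005, 0.01))
  expect_setequal(unique(gs$results$gamma), c(0.1, 0.5, 0.75))
  expect_s3_class(gs$model, "baa_classifier")
  expect_true(max(gs$results$val_accuracy, na.rm = TRUE) ==
                max(gs$model$history$val_accuracy))
  single <- grid_search_bone_age(imgs, lrs = 0.005, gammas = 0.5,
                                 fixed = fixed, labels = labels,
                                 validation = list(images = imgs,
                                                   labels = labels))
  expect_identical(nrow(single$results), 1L)
})

test_that("predictions are deterministic softmax distributions over 14 ages", {
  model <- baa_classifier("female", seed = 8)
  img <- matrix(runif(512 * 512), 512, 512)
  p1 <- predict(model, img)
  p2 <- predict(model, img)
  expect_identical(p1$probabilities, p2$probabilities)
  expect_length(p1$probabilities, 14)
  expect_equal(sum(p1$probabilities), 1, tolerance = 1e-6)
  expect_true(all(diff(p1$topk$probability) <= 0))
  expect_identical(nrow(p1$topk), 5L)
  expect_identical(nrow(predict(model, img, topk = 3)$topk), 3L)
  expect_true(p1$top1 %in% 5:18)
  expect_error(predict(model, matrix(0.5, 100, 80)),
               class = "baa_shape_error")
})

test_that("augmentation does not hurt validation accuracy (non-inferiority)", {
  # two maximally separated classes keep the desk-scale runs short; the
  # comparison mirrors the augmented-vs-plain training contrast
  coh <- generate_cohort(8, sexes = "female", seed = 31, classes = c(5L, 18L),
                         size_range = c(512L, 700L))
  pre <- lapply(coh, function(ph) {
    n <- normalize_phantom(ph)
    vision_pipeline(n$radiograph, n$truth$hand_mask)
  })
  labs <- vapply(pre, function(r) r$bone_age_label, integer(1))
  val <- list(images = pre, labels = labs)
  acc <- function(seed, aug) {
    cfg <- train_config(epochs = 10, base_lr = 0.03, gamma = 0.5,
                        batch_size = 8, seed = seed,
                        finetune_depth = "scratch", augmentation = aug)
    fit <- train_bone_age_classifier(pre, cfg, validation = val)
    max(fit$history$val_accuracy)
  }
  seeds <- 1:5
  plain <- vapply(seeds, function(s) acc(s, NULL), numeric(1))
  aug <- vapply(seeds, function(s) acc(s, default_augmentation_config()),
                numeric(1))
  diffs <- aug - plain
  margin <- 2 * stats::sd(diffs) / sqrt(length(diffs))
  expect_gte(mean(diffs), -max(margin, 1e-8))
})

test_that("YAML run configurations round-trip into train_config", {
  f <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("epochs: 20", "base_lr: 0.01", "batch_size: 8",
               "augmentation:", "  switch_prob: 0.4",
               "  enabled:", "    rotate: true", "    resize: false",
               "    shear: true", "    pixel: true"), f)
  cfg <- read_run_config(f)
  expect_identical(cfg$epochs, 20L)
  expect_identical(cfg$base_lr, 0.01)
  expect_identical(augmentation_cardinality(cfg$augmentation), 61 * 121 * 100)
  expect_identical(cfg$augmentation$switch_prob, 0.4)
})
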