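test_that("evaluation metrics match hand-worked arithmetic", {
  perfect <- evaluate_predictions(c(5L, 9L, 14L), c(5L, 9L, 14L))
  expect_identical(perfect$top1_accuracy, 1)
  expect_identical(perfect$rmse, 0)
  ev <- evaluate_predictions(c(7L, 10L), c(5L, 9L))
  expect_identical(ev$top1_accuracy, 0)
  expect_identical(ev$within1_accuracy, 0.5)
  expect_identical(ev$within2_accuracy, 1)
  expect_equal(ev$rmse, sqrt((4 + 1) / 2))
  expect_error(evaluate_predictions(1:3, 1:4), class = "baa_shape_error")
})

test_that("within-k accuracies are monotone for random prediction sets", {
  set.seed(41)
  for (i in 1:20) {
    n <- sample(5:60, 1)
    ev <- evaluate_predictions(sample(5:18, n, TRUE), sample(5:18, n, TRUE))
    expect_lte(ev$top1_accuracy, ev$within1_accuracy)
    expect_lte(ev$within1_accuracy, ev$within2_accuracy)
    expect_lte(ev$within2_accuracy, 1)
  }
})

test_that("mAP is 1 for perfect rankings and prevalence-like when shuffled", {
  set.seed(17)
  n <- 400
  truths <- sample(5:18, n, TRUE)
  probs <- matrix(0.001, n, 14)
  probs[cbind(seq_len(n), match(truths, 5:18))] <- 0.9
  probs <- probs / rowSums(probs)
  ev <- evaluate_predictions(truths, truths, probs)
  expect_equal(ev$map, 1)
  # label-shuffled probabilities: AP per class concentrates near prevalence
  sh <- probs[sample(n), ]
  ev2 <- evaluate_predictions(truths, truths, sh)
  expect_lt(abs(ev2$map - 1 / 14), 0.05)
})

test_that("mIoU counts pixels exactly", {
  a <- matrix(FALSE, 20, 20); a[1:10, 1:10] <- TRUE
  expect_identical(miou(list(a), list(a)), 1)
  b <- matrix(FALSE, 20, 20); b[11:20, 11:20] <- TRUE
  expect_identical(miou(list(a), list(b)), 0)
  # 100x100 rectangles overlapping on 100x50 -> IoU = 5000/15000
  p <- matrix(FALSE, 200, 200); p[1:100, 1:100] <- TRUE
  t2 <- matrix(FALSE, 200, 200); t2[1:100, 51:150] <- TRUE
  expect_equal(miou(list(p), list(t2)), 1 / 3)
  # mean over pairs
  expect_equal(miou(list(a, p), list(a, t2)), (1 + 1 / 3) / 2)
  expect_error(miou(list(matrix(FALSE, 20, 20)), list(matrix(FALSE, 20, 20))),
               class = "baa_undefined_iou")
  # empty prediction against non-empty truth is a plain IoU of zero
  expect_identical(miou(list(matrix(FALSE, 20, 20))[1], list(a)), 0)
  expect_error(miou(list(a), list(matrix(TRUE, 5, 5))),
               class = "baa_shape_error")
})

test_that("the patch/stride sweep evaluates every grid cell", {
  m <- shared_detector()
  corpus <- shared_test_phantoms()[1:3]
  tab <- patch_stride_sweep(corpus, function(ps) m,
                            strides = c(4L, 8L), patch_sizes = 32L)
  expect_identical(nrow(tab), 2L)
  expect_identical(sort(tab$stride), c(4L, 8L))
  expect_true(all(tab$miou > 0 & tab$miou <= 1))
  single <- patch_stride_sweep(corpus[1], function(ps) m,
                               strides = 4L, patch_sizes = 32L)
  expect_identical(dim(single), c(1L, 3L))
})

test_that("maturity stages follow the sex-specific lower-inclusive bins", {
  expect_identical(as.character(maturity_stage("female", 6)), "prepuberty")
  expect_identical(as.character(maturity_stage("male", 15)), "late_puberty")
  # boundary ages are lower-inclusive
  expect_identical(as.character(maturity_stage("female", 13)), "late_puberty")
  expect_identical(as.character(maturity_stage("female", 7)),
                   "early_mid_puberty")
  expect_identical(as.character(maturity_stage("female", 15)), "postpuberty")
  expect_identical(as.character(maturity_stage("male", 9)),
                   "early_mid_puberty")
  expect_identical(as.character(maturity_stage("male", 16)), "late_puberty")
  expect_identical(as.character(maturity_stage("male", 17)), "postpuberty")
  expect_error(maturity_stage("female", -1), class = "baa_domain_error")
  # vectorized, sex-specific bins at the same age
  st <- maturity_stage(c("female", "male"), c(14, 13))
  expect_identical(as.character(st), c("late_puberty", "early_mid_puberty"))
})

test_that("occlusion maps localize what a toy linear model looks at", {
  ab <- asNamespace("autobaa")
  # model whose class-5 logit is the mean intensity of rows 65..96,
  # cols 65..96 (a 32x32 region): occlusion changes its output only when
  # the occluder intersects that region
  W <- matrix(0, 224 * 224, 14)
  sel <- as.vector(outer(65:96, (65:96 - 1) * 224, "+"))
  W[sel, 1] <- 1 / length(sel) * 50
  layers <- list(ab$nn_flatten(), list(type = "fc", nin = 224 * 224,
                                       nout = 14, group = "fc", relu = FALSE,
                                       W = W, b = numeric(14)))
  model <- structure(list(net = ab$nn_build(layers, c(224, 224, 1), 14),
                          sex = "female", backbone = "small",
                          classes = 5:18, pretrained = FALSE),
                     class = "baa_classifier")
  img <- matrix(runif(224 * 224, 0.3, 0.9), 224, 224)
  amap <- occlusion_map(model, img, occluder_size = 16L, occluder_stride = 8L,
                        target_class = 5L)
  expect_identical(dim(amap$values), c(27L, 27L))
  touches <- outer(amap$row_offsets, amap$col_offsets, function(ro, co)
    ro < 96 & (ro + 16) > 64 & co < 96 & (co + 16) > 64)
  expect_true(all(abs(amap$values[!touches]) < 1e-9))
  expect_true(all(amap$values[touches & abs(amap$values) > 0] > 0))
  # exhaustive-occlusion oracle at a handful of positions
  for (q in list(c(1, 1), c(9, 9), c(13, 20))) {
    r0 <- amap$row_offsets[q[1]]; c0 <- amap$col_offsets[q[2]]
    occ <- img; occ[r0 + 1:16, c0 + 1:16] <- 0
    p_occ <- exp(50 * mean(occ[65:96, 65:96])) /
      (exp(50 * mean(occ[65:96, 65:96])) + 13)
    p_orig <- exp(50 * mean(img[65:96, 65:96])) /
      (exp(50 * mean(img[65:96, 65:96])) + 13)
    expect_lt(abs(amap$values[q[1], q[2]] - (p_orig - p_occ)), 1e-9)
  }
})

test_that("degenerate occlusion configurations behave per contract", {
  ab <- asNamespace("autobaa")
  # constant model: zero weights -> uniform output, all-zero map
  layers <- list(ab$nn_flatten(),
                 list(type = "fc", nin = 224 * 224, nout = 14, group = "fc",
                      relu = FALSE, W = matrix(0, 224 * 224, 14),
                      b = numeric(14)))
  model <- structure(list(net = ab$nn_build(layers, c(224, 224, 1), 14),
                          sex = "female", classes = 5:18, pretrained = FALSE),
                     class = "baa_classifier")
  img <- matrix(runif(224 * 224), 224, 224)
  expect_warning(amap <- occlusion_map(model, img, target_class = 7L),
                 class = "baa_misclassified")
  expect_true(all(abs(amap$values) < 1e-12))
  # occluder as large as the image: a single position
  suppressWarnings(one <- occlusion_map(model, img, occluder_size = 224L,
                                        occluder_stride = 8L,
                                        target_class = 7L))
  expect_identical(dim(one$values), c(1L, 1L))
  expect_error(suppressWarnings(occlusion_map(model, img, occluder_size = 300L)),
               class = "baa_geometry_error")
})
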