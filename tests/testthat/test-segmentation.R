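test_that("sliding-window scoring enumerates the expected patch grid", {
  m <- shared_separable_detector()
  ph <- normalize_phantom(generate_phantom(
    phantom_spec(height = 600, width = 500, seed = 2)))
  sc <- autobaa:::score_grid(m, ph$radiograph$pixels / 255, 32L, 4L)
  expect_identical(nrow(sc), 14641L)  # (floor((512-32)/4)+1)^2 = 121^2
  expect_identical(ncol(sc), 5L)
  expect_equal(unname(rowSums(sc)), rep(1, nrow(sc)), tolerance = 1e-9)
})

test_that("whole-image scoring matches independent per-patch scoring", {
  # the shared-computation path must be exactly the sliding window
  m <- shared_separable_detector()
  ph <- normalize_phantom(generate_phantom(
    phantom_spec(height = 200, width = 170, seed = 3)))
  x01 <- ph$radiograph$pixels[1:96, 1:88] / 255
  fast <- autobaa:::score_grid(m, x01, 32L, 4L)
  X <- autobaa:::im2col_batch(as.numeric(x01), 96L, 88L, 1L, 1L, 32L, 4L, 0L)
  slow <- autobaa:::score_patch_array(m, array(t(X), c(32, 32, 1, nrow(X))))
  expect_equal(fast, slow, tolerance = 1e-12)
})

test_that("constant scores give a uniform label map of the argmax class", {
  sc <- matrix(rep(c(0.1, 0.2, 0.4, 0.2, 0.1), each = 121^2), 121^2, 5)
  lab <- autobaa:::aggregate_position_scores(sc, 512L, 512L, 32L, 4L)
  expect_identical(unique(as.vector(lab)), 3L)
  # ties break toward the earlier class in the fixed order
  sc_tie <- matrix(0.2, 121^2, 5)
  lab_tie <- autobaa:::aggregate_position_scores(sc_tie, 512L, 512L, 32L, 4L)
  expect_identical(unique(as.vector(lab_tie)), 1L)
})

test_that("one-hot center-class scores reconstruct the truth away from borders", {
  # oracle model: scores = one-hot of the ground-truth class at the patch
  # center; with stride 1 the vote average must reproduce the class field
  # except within floor(S/2) of the image border
  S <- 8L
  # the earlier class of the fixed order sits on the tie-winning side
  truth_v <- matrix(3L, 64, 64); truth_v[, 1:30] <- 2L
  truth_h <- matrix(4L, 64, 64); truth_h[1:21, ] <- 1L
  for (truth in list(truth_v, truth_h)) {
    nr <- 64L - S + 1L
    centers <- seq_len(nr) + S %/% 2L
    tc <- truth[centers, centers]
    sc <- matrix(0, nr * nr, 5)
    sc[cbind(seq_len(nr * nr), as.vector(tc))] <- 1
    lab <- autobaa:::aggregate_position_scores(sc, 64L, 64L, S, 1L)
    interior <- (S %/% 2L + 1L):(64L - S %/% 2L)
    mism <- lab[interior, interior] != truth[interior, interior]
    expect_identical(sum(mism), 0L)
  }
})

test_that("label maps collapse to hand grids by bone|tissue", {
  m <- matrix(3L, 5, 5)
  expect_false(any(labelmap_to_hand(m)))
  m[2, 2] <- 1L; m[4, 4] <- 2L
  hand <- labelmap_to_hand(m)
  expect_identical(which(hand), c(7L, 19L))
  expect_identical(sum(hand) + sum(!hand), 25L)
})

test_that("mask generation keeps the largest component and fills holes", {
  # flood-fill oracle for hole counting
  flood_holes <- function(m) {
    lab <- autobaa:::conncomp4(!m)
    border_labs <- unique(c(lab[1, ], lab[nrow(m), ], lab[, 1], lab[, ncol(m)]))
    sum(lab > 0 & !(lab %in% border_labs))
  }
  grid <- matrix(FALSE, 100, 100)
  grid[10:80, 10:70] <- TRUE       # large blob, area 71x61
  grid[25:27, 30:32] <- FALSE      # 3x3 interior hole
  grid[90:95, 90:95] <- TRUE       # distant small blob
  expect_identical(flood_holes(grid), 9L)
  mask <- generate_mask(grid)
  expect_identical(sum(mask), 71L * 61L)          # hole filled: +9
  expect_false(any(mask[90:95, 90:95]))           # small blob removed
  # idempotence and single-component output
  expect_identical(unclass(generate_mask(mask)), unclass(mask))
  expect_identical(max(autobaa:::conncomp4(mask)), 1L)
  expect_error(generate_mask(matrix(FALSE, 4, 4)),
               class = "baa_empty_segmentation")
})

test_that("component ties break by the first pixel in row-major order", {
  g <- matrix(FALSE, 10, 10)
  g[6:7, 1:2] <- TRUE   # area 4, top-left later in row-major order
  g[2:3, 5:6] <- TRUE   # area 4, appears first scanning rows
  mask <- generate_mask(g)
  expect_true(all(mask[2:3, 5:6]))
  expect_false(any(mask[6:7, 1:2]))
})

test_that("the vision pipeline masks, centers and stays in range", {
  # whole-image constant content: every stage is the identity
  const <- radiograph(matrix(77L, 64, 64))
  out <- vision_pipeline(const, matrix(TRUE, 64, 64))
  expect_identical(out$pixels, const$pixels)

  # off-center blob is recentered to the image center
  px <- matrix(0L, 512, 512)
  px[41:140, 31:90] <- 180L   # 100x60 blob
  mask <- matrix(FALSE, 512, 512)
  mask[41:140, 31:90] <- TRUE
  out <- vision_pipeline(radiograph(px), mask)
  m2 <- attr(out, "mask")
  rc <- mean(range(which(rowSums(m2) > 0)))
  cc <- mean(range(which(colSums(m2) > 0)))
  expect_lte(abs(rc - 256.5), 0.5)
  expect_lte(abs(cc - 256.5), 0.5)

  # artifacts outside the mask are removed and background stays zero
  px[200, 400] <- 255L
  out2 <- vision_pipeline(radiograph(px), mask)
  expect_true(all(out2$pixels[!attr(out2, "mask")] == 0L))
  expect_true(all(out2$pixels >= 0L & out2$pixels <= 255L))
  expect_error(vision_pipeline(radiograph(px), matrix(FALSE, 512, 512)),
               class = "baa_empty_segmentation")
  expect_error(vision_pipeline(radiograph(px), matrix(TRUE, 10, 10)),
               class = "baa_shape_error")
})

test_that("in-mask equalization spreads the intensity histogram", {
  ph <- normalize_phantom(generate_phantom(
    phantom_spec(height = 600, width = 480, seed = 6)))
  out <- vision_pipeline(ph$radiograph, ph$truth$hand_mask)
  v <- out$pixels[attr(out, "mask")]
  # equalized in-mask intensities should span most of the dynamic range
  expect_gt(diff(range(v)), 200)
  expect_identical(dim(out$pixels), dim(ph$radiograph$pixels))
})
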