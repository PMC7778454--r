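test_that("half-max thresholding is inclusive and handles edge cases", {
  expect_equal(half_max_voxels(c(1.0, 0.6, 0.4)), c(1L, 2L))
  expect_equal(half_max_voxels(c(1.0, 0.5)), c(1L, 2L))
  expect_equal(half_max_voxels(rep(0.3, 7)), 1:7)
  expect_equal(half_max_voxels(c(-1, 0.6, 0.4)), c(1L, 2L))  # absolute values
  expect_warning(out <- half_max_voxels(numeric(3)), "all-zero")
  expect_length(out, 0)
})

test_that("bias, spread and BSM match hand computations", {
  pos <- rbind(c(1, 0, 0), c(0, 0, 0), c(2, 0, 0), c(4, 0, 0))

  r1 <- bias_spread(1, pos, c(1, 0, 0))
  expect_equal(c(r1$bias, r1$spread, r1$bsm), c(0, 0, 0))

  r2 <- bias_spread(c(2, 3), pos, c(1, 0, 0))
  expect_equal(r2$bias, 0)
  expect_equal(r2$spread, 1)
  expect_equal(r2$bsm, 1)

  r3 <- bias_spread(c(2, 4), pos, c(0, 0, 0))
  expect_equal(r3$bias, 2)
  expect_equal(r3$spread, 4)
  expect_equal(r3$bsm, sqrt(8))

  expect_error(bias_spread(integer(0), pos, c(0, 0, 0)), "empty")
})

test_that("BSM is invariant under rigid motions and monotone in outliers", {
  set.seed(4)
  pos <- matrix(rnorm(60), 20, 3)
  ctr <- c(0.3, -0.2, 0.5)
  valid <- c(2, 5, 9, 14, 17)
  base <- bias_spread(valid, pos, ctr)

  shift <- c(5, -3, 11)
  r_t <- bias_spread(valid, sweep(pos, 2, -shift), ctr + shift)
  expect_equal(r_t$bias, base$bias, tolerance = 1e-10)
  expect_equal(r_t$spread, base$spread, tolerance = 1e-10)
  expect_equal(r_t$bsm, base$bsm, tolerance = 1e-10)

  th <- 0.7
  Rz <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  pos_r <- sweep(sweep(pos, 2, ctr) %*% t(Rz), 2, -ctr)
  r_r <- bias_spread(valid, pos_r, ctr)
  expect_equal(r_r$bias, base$bias, tolerance = 1e-10)
  expect_equal(r_r$bsm, base$bsm, tolerance = 1e-10)

  # adding a voxel farther from the center of mass than the spread radius
  # cannot decrease the spread
  far <- base$center_of_mass + c(3 * sqrt(base$spread), 0, 0)
  pos2 <- rbind(pos, far)
  r_m <- bias_spread(c(valid, 21), pos2, ctr)
  expect_gte(r_m$spread, base$spread)
})

test_that("two-spot rule: detection, partitioning, straddling blob", {
  # lattice of voxels around two centers 20 mm apart
  ca <- c(-10, 0, 0)
  cb <- c(10, 0, 0)
  blobA <- sweep(matrix(rnorm(15, sd = 1.5), 5, 3), 2, ca, "+")
  blobB <- sweep(matrix(rnorm(15, sd = 1.5), 5, 3), 2, cb, "+")
  pos <- rbind(blobA, blobB)

  # all valid voxels nearer A: B undetected
  vals <- c(rep(1, 5), rep(0.1, 5))
  res <- two_spot_assessment(vals, pos, ca, cb, spacing_mm = 2)
  expect_true(res$A$detected)
  expect_false(res$B$detected)
  expect_true(is.na(res$B$bsm))

  # two clean blobs: each spot scored from its own voxels
  vals2 <- c(rep(1, 5), rep(0.9, 5))
  res2 <- two_spot_assessment(vals2, pos, ca, cb, spacing_mm = 2)
  expect_true(res2$A$detected && res2$B$detected)
  expect_setequal(res2$A$valid_voxel_ids, 1:5)
  expect_setequal(res2$B$valid_voxel_ids, 6:10)
  expect_equal(res2$A$bsm, bias_spread(1:5, pos, ca)$bsm)

  # a single contiguous blob straddling both centers is used for both spots
  line <- cbind(seq(-12, 12, by = 2), 0, 0)
  vals3 <- rep(1, nrow(line))
  res3 <- two_spot_assessment(vals3, line, ca, cb, spacing_mm = 2)
  expect_true(res3$A$detected && res3$B$detected)
  expect_setequal(res3$A$valid_voxel_ids, res3$B$valid_voxel_ids)
  expect_equal(res3$A$spread, res3$B$spread)

  expect_error(two_spot_assessment(vals3, line, ca, ca), "distinct")
})

test_that("BSM agrees with a brute-force oracle on random voxel sets", {
  # independent re-computation with explicit loops
  oracle <- function(valid, pos, ctr) {
    n <- length(valid)
    com <- c(0, 0, 0)
    for (i in valid) com <- com + pos[i, ] / n
    bias <- sqrt(sum((com - ctr)^2))
    spread <- 0
    for (i in valid) spread <- spread + sum((pos[i, ] - com)^2) / n
    c(bias, spread, sqrt(bias^2 + spread))
  }
  set.seed(5)
  for (rep in 1:100) {
    nv <- sample(1:20, 1)
    pos <- matrix(rnorm(3 * (nv + 5), sd = 10), nv + 5, 3)
    valid <- sample(nv + 5, nv)
    ctr <- rnorm(3, sd = 5)
    got <- bias_spread(valid, pos, ctr)
    want <- oracle(valid, pos, ctr)
    expect_equal(c(got$bias, got$spread, got$bsm), want, tolerance = 1e-10)
  }
})
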