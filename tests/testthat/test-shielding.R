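test_that("isotropic shielding is the diagonal mean and rotation-invariant", {
  expect_equal(isotropicShielding(diag(281.1, 3)), 281.1)
  expect_equal(isotropicShielding(diag(c(280, 281, 282))), 281)
  expect_error(isotropicShielding(matrix(c(1, NA, rep(0, 7)), 3)), "finite")

  set.seed(13)
  for (rep in 1:10) {
    m <- matrix(rnorm(9, 280, 5), 3)
    s <- (m + t(m)) / 2
    r <- randomRotation()
    expect_equal(isotropicShielding(r %*% s %*% t(r)),
                 isotropicShielding(s), tolerance = 1e-10)
  }
})

test_that("bootstrap averaging reproduces constants and is seed-deterministic", {
  const <- bootstrapAverage(rep(281.5, 35), seed = 3)
  expect_equal(ensembleMean(const), 281.5)
  expect_true(all(const@bootMeans == 281.5))
  expect_equal(bootstrapError(const), 0)

  set.seed(400)
  vals <- rnorm(35, 281, 1)
  r1 <- bootstrapAverage(vals, seed = 42)
  r2 <- bootstrapAverage(vals, seed = 42)
  expect_identical(r1@bootMeans, r2@bootMeans)
  expect_identical(ensembleMean(r1), ensembleMean(r2))
  expect_identical(r1@ci, r2@ci)

  expect_error(bootstrapAverage(281), "at least 2")
})

test_that("the trailing-window mean is unbiased for the sample mean", {
  set.seed(77)
  vals <- rnorm(35, 281, 1)
  devs <- vapply(1:200, function(s)
    ensembleMean(bootstrapAverage(vals, seed = s)) - mean(vals), numeric(1))
  # Monte-Carlo oracle: mean bootstrap deviation ~ 0 within 3 SE
  expect_lte(abs(mean(devs)), 3 * sd(devs) / sqrt(length(devs)))
})

test_that("bootstrap Err tracks the analytic standard error of the mean", {
  set.seed(88)
  vals <- rnorm(35, 281, 1)
  r <- bootstrapAverage(vals, seed = 5)
  analytic <- sd(vals) / sqrt(35)
  expect_lt(abs(bootstrapError(r) - analytic) / analytic, 0.25)

  # symmetric inputs give an approximately symmetric CI about the centre
  mid <- mean(r@bootMeans)
  expect_lt(abs((r@ci[2] - mid) - (mid - r@ci[1])), bootstrapError(r))
})

test_that("the bootstrap running mean converges within Err", {
  set.seed(55)
  for (s in 1:5) {
    r <- bootstrapAverage(rnorm(35, 281, 1), seed = s)
    cc <- convergenceCheck(r)
    expect_true(cc$converged)
  }
})

test_that("per-snapshot site averaging happens before resampling", {
  tens <- array(0, c(4, 3, 3))
  for (i in 1:4) tens[i, , ] <- diag(c(280, 282, 280, 284)[i], 3)
  ss <- new("ShieldingSet", tensors = tens,
            snapshot = c("a", "a", "b", "b"), site = c("P1", "P2", "P1", "P2"),
            truth = list())
  r <- bootstrapAverage(ss, seed = 1)
  # snapshots collapse to (281, 282); resampled means stay within range
  expect_true(all(r@bootMeans >= 281 & r@bootMeans <= 282))
  expect_identical(length(r@values), 2L)
})

test_that("useAll averages the full iteration record", {
  set.seed(60)
  vals <- rnorm(35, 281, 1)
  r <- bootstrapAverage(vals, seed = 9, useAll = TRUE)
  expect_equal(ensembleMean(r), mean(r@bootMeans))
  rTail <- bootstrapAverage(vals, seed = 9)
  expect_equal(ensembleMean(rTail), mean(tail(rTail@bootMeans, 15)))
})

test_that("speciation-weighted averaging pairs the fraction with its species", {
  expect_equal(weightedAverage(280, 278, 1), 280)
  expect_equal(weightedAverage(280, 278, 0), 278)
  expect_equal(weightedAverage(280, 278, 0.5), 279)
  # composed with speciation at pH = pKa2: the arithmetic mean
  expect_equal(weightedAverage(280.9, 278.7, speciationFraction(7.2, 7.2)),
               mean(c(280.9, 278.7)))
  # acidic pH weights the diprotonated species
  acid <- weightedAverage(282, 278, speciationFraction(4.5, 7.2))
  expect_gt(acid, 281.9)
  # output always between the inputs
  set.seed(3)
  for (rep in 1:20) {
    s1 <- rnorm(1, 280, 2); s2 <- rnorm(1, 280, 2)
    w <- runif(1)
    out <- weightedAverage(s1, s2, w)
    expect_gte(out, min(s1, s2) - 1e-12)
    expect_lte(out, max(s1, s2) + 1e-12)
  }
  expect_error(weightedAverage(280, 278, 1.2), "\\[0, 1\\]")
})

test_that("shift referencing round-trips the calibration pair exactly", {
  cal <- calibrateReference(deltaObs = 0.04, sigmaObs = 281.1)
  expect_equal(cal@sigmaRef, 281.14)
  expect_equal(shieldingToShift(281.1, cal), 0.04)
  expect_equal(calibrateReference(0, 281.1)@sigmaRef, 281.1)

  # strictly decreasing in the shielding
  s <- seq(275, 285, by = 0.5)
  expect_true(all(diff(shieldingToShift(s, cal)) < 0))
})

test_that("shielding pipeline recovers the planted mean within 3 Err", {
  hits <- vapply(1:40, function(s) {
    ss <- genShieldingSet(shieldingSetSpec(n = 35, mean = 281.1, sd = 1,
                                           seed = s))
    r <- bootstrapAverage(ss, seed = s)
    abs(ensembleMean(r) - mean(isotropicShielding(ss))) <= 3 * bootstrapError(r)
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("tensor TSV and magres round-trips preserve the set", {
  ss <- genShieldingSet(shieldingSetSpec(n = 5, mean = 280, sd = 1,
                                         anisotropy = 3, seed = 2))
  path <- withr::local_tempfile(fileext = ".tsv")
  writeShieldingTsv(ss, path)
  back <- readShieldingTsv(path)
  expect_equal(back@tensors, ss@tensors, tolerance = 1e-12)
  expect_identical(back@snapshot, ss@snapshot)

  mg <- withr::local_tempfile(fileext = ".magres")
  t1 <- ss@tensors[1, , ]
  writeLines(c("#$magres-abinitio-v1.0", "[magres]",
               "units ms ppm",
               paste("ms P 1", paste(sprintf("%.6f", t(t1)), collapse = " ")),
               paste("ms H 2", paste(rep("10.0", 9), collapse = " ")),
               "[/magres]"), mg)
  m <- readMagres(mg)
  expect_identical(dim(m@tensors)[1], 2L)
  expect_equal(m@tensors[1, , ], t1, tolerance = 1e-6)
  p <- readMagres(mg, label = "P")
  expect_identical(dim(p@tensors)[1], 1L)
  expect_identical(p@site, "P1")
})
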