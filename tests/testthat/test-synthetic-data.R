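test_that("noise-free cluster snapshots hit the construction targets exactly", {
  fr <- genClusterSnapshot(clusterSpec(nCa = 3, nHPO4 = 3, waters = 10,
                                       sd = 0))
  cl <- findClusters(fr)
  expect_length(cl, 1L)
  expect_identical(unname(composition(cl[[1]])[c("nCa", "nP")]), c(3L, 3L))
  expect_identical(hydrationCount(fr, cl[[1]])$count, 10L)

  # all first-shell contacts exactly at the planted distance
  fr22 <- genClusterSnapshot(clusterSpec(nCa = 2, nHPO4 = 2, waters = 4,
                                         sd = 0))
  a <- atoms(fr22)
  ca <- as.matrix(a[a$role == "Ca", c("x", "y", "z")])
  p <- as.matrix(a[a$role == "P", c("x", "y", "z")])
  d <- as.vector(pncnmr:::.pairDist(ca, p))
  first <- d[abs(d - 3.0) < 0.3]
  expect_true(length(first) >= 2)
  expect_equal(first, rep(3.0, length(first)), tolerance = 1e-9)
})

test_that("noisy snapshots keep the distance-histogram mode at the planted shell", {
  fr <- genClusterSnapshot(clusterSpec(nCa = 4, nHPO4 = 5, waters = 8,
                                       sd = 0.05, seed = 9))
  # brute-force distance enumeration on the generated frame
  a <- atoms(fr)
  ca <- as.matrix(a[a$role == "Ca", c("x", "y", "z")])
  p <- as.matrix(a[a$role == "P", c("x", "y", "z")])
  d <- numeric()
  for (i in seq_len(nrow(ca))) for (j in seq_len(nrow(p)))
    d <- c(d, sqrt(sum((ca[i, ] - p[j, ])^2)))
  h <- hist(d[d >= 2 & d <= 6], breaks = seq(2, 6, by = 0.1), plot = FALSE)
  expect_lte(abs(h$mids[which.max(h$counts)] - 3.0), 0.1)
})

test_that("generators are deterministic under a fixed seed", {
  s <- clusterSpec(nCa = 3, nHPO4 = 3, waters = 6, sd = 0.05, seed = 4)
  expect_identical(atoms(genClusterSnapshot(s)), atoms(genClusterSnapshot(s)))

  ts <- trajectorySpec(nFrames = 12, formationFrame = 5, seed = 8)
  t1 <- genTrajectory(ts, s)
  t2 <- genTrajectory(ts, s)
  expect_identical(atoms(getFrame(t1, 7)), atoms(getFrame(t2, 7)))

  ss <- shieldingSetSpec(n = 35, mean = 281.1, sd = 1, seed = 3)
  expect_identical(isotropicShielding(genShieldingSet(ss)),
                   isotropicShielding(genShieldingSet(ss)))
})

test_that("generators leave the caller's RNG stream untouched", {
  set.seed(99)
  ahead <- rnorm(3)
  set.seed(99)
  invisible(genShieldingSet(shieldingSetSpec(seed = 5)))
  invisible(genClusterSnapshot(clusterSpec(sd = 0.05, seed = 5)))
  expect_identical(rnorm(3), ahead)
})

test_that("trajectory frames respect the planted formation index", {
  cs <- clusterSpec(nCa = 3, nHPO4 = 3, waters = 8, sd = 0.02, seed = 2)
  tr <- genTrajectory(trajectorySpec(nFrames = 10, formationFrame = 6,
                                     seed = 2), cs)
  for (i in 1:5) {
    fr <- getFrame(tr, i)
    a <- atoms(fr)
    ions <- as.matrix(a[a$role %in% c("Ca", "P"), c("x", "y", "z")])
    d <- pncnmr:::.pairDist(ions, ions, fr@box)
    diag(d) <- Inf
    expect_gt(min(d), 6)
    expect_length(findClusters(fr), 0L)
  }
  for (i in 6:10) {
    cl <- findClusters(getFrame(tr, i))
    expect_length(cl, 1L)
    expect_identical(unname(composition(cl[[1]])[c("nCa", "nP")]), c(3L, 3L))
  }
})

test_that("degenerate formation indices produce all/one clustered frames", {
  cs <- clusterSpec(nCa = 2, nHPO4 = 2, waters = 4, sd = 0, seed = 1)
  allC <- genTrajectory(trajectorySpec(nFrames = 4, formationFrame = 1,
                                       seed = 1), cs)
  expect_true(all(vapply(seq_len(4), function(i)
    length(findClusters(getFrame(allC, i))) == 1L, logical(1))))

  oneC <- genTrajectory(trajectorySpec(nFrames = 4, formationFrame = 4,
                                       seed = 1), cs)
  nclust <- vapply(seq_len(4), function(i)
    length(findClusters(getFrame(oneC, i))), integer(1))
  expect_identical(nclust, c(0L, 0L, 0L, 1L))
})

test_that("free diprotonated phosphates never join the planted cluster", {
  cs <- clusterSpec(nCa = 3, nHPO4 = 3, waters = 6, sd = 0.02, seed = 6)
  tr <- genTrajectory(trajectorySpec(nFrames = 8, formationFrame = 3,
                                     nFreeH2PO4 = 3, seed = 6), cs)
  for (i in 3:8) {
    cl <- findClusters(getFrame(tr, i))
    expect_length(cl, 1L)
    expect_identical(composition(cl[[1]])[["nH2PO4"]], 0L)
    expect_identical(composition(cl[[1]])[["nHPO4"]], 3L)
  }
})

test_that("a too-small box is rejected", {
  expect_error(
    genTrajectory(trajectorySpec(nFrames = 3, formationFrame = 2,
                                 boxEdge = 2, seed = 1),
                  clusterSpec(nCa = 3, nHPO4 = 3, waters = 5, seed = 1)),
    "box too small")
})

test_that("shielding sets have exact isotropic parts and converge in mean", {
  pure <- genShieldingSet(shieldingSetSpec(n = 5, mean = 281.1, sd = 0,
                                           anisotropy = 0, seed = 1))
  for (i in 1:5)
    expect_equal(pure@tensors[i, , ], diag(281.1, 3))

  # anisotropy never leaks into the isotropic part
  an <- genShieldingSet(shieldingSetSpec(n = 20, mean = 280, sd = 0.5,
                                         anisotropy = 10, seed = 2))
  noAn <- genShieldingSet(shieldingSetSpec(n = 20, mean = 280, sd = 0.5,
                                           anisotropy = 0, seed = 2))
  expect_equal(isotropicShielding(an), isotropicShielding(noAn))

  # central-limit bound at large n
  big <- genShieldingSet(shieldingSetSpec(n = 1e4, mean = 281.1, sd = 1,
                                          seed = 7))
  expect_lte(abs(mean(isotropicShielding(big)) - 281.1), 3 / 100)
})

test_that("fixture tables expose the per-pH rows and reject absent keys", {
  tabs <- phosphateShiftTables()
  expect_equal(lookupShiftRow(tabs$experimental, 6)$deltaPi, 0.58)
  expect_equal(lookupShiftRow(tabs$experimental, 7)$gammaPNC, 140)
  expect_equal(lookupShiftRow(tabs$computed, 8)$sigmaPNC, 278.4)
  expect_error(lookupShiftRow(tabs$experimental, 9), "no fixture row")

  long <- assembleShiftTable()
  expect_identical(nrow(long), 6L)
  expect_false(anyDuplicated(long[, c("pH", "species")]) > 0)
})
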