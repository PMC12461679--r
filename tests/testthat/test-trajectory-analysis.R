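test_that("Ca-P distance RMSD matches its closed form and brute force", {
  ca <- rbind(c(0, 0, 0), c(5, 0, 0))
  ph <- list(list(pos = c(0, 3, 0), nH = 1), list(pos = c(5, 3, 0), nH = 1))
  ref <- makeFrame(ca, ph)
  expect_identical(rmsdCaP(ref, ref), 0)

  # one of N pair distances changed by Delta -> Delta / sqrt(N)
  ph2 <- list(list(pos = c(0, 4, 0), nH = 1), list(pos = c(5, 3, 0), nH = 1))
  moved <- makeFrame(ca, ph2)
  n <- 4  # 2 Ca x 2 P pairs
  d0 <- sqrt(sum((c(0, 3, 0))^2))
  dRef <- c(3, sqrt(25 + 9), sqrt(25 + 9), 3)
  dNew <- c(4, sqrt(25 + 16), sqrt(25 + 9), 3)
  expect_equal(rmsdCaP(moved, ref), sqrt(mean((dNew - dRef)^2)))

  # randomized frames against the double-loop oracle
  set.seed(21)
  for (rep in 1:5) {
    caR <- matrix(runif(9, 0, 20), 3)
    phR <- lapply(1:3, function(i) list(pos = runif(3, 0, 20), nH = 1))
    f1 <- makeFrame(caR, phR)
    f2 <- makeFrame(caR + matrix(rnorm(9, 0, 1), 3), phR)
    expect_equal(rmsdCaP(f2, f1), bruteRmsd(f2, f1), tolerance = 1e-12)
  }

  oneCa <- makeFrame(matrix(c(0, 0, 0), 1), ph)
  expect_error(rmsdCaP(oneCa, ref), "atom ordering")
})

test_that("formation detection finds plateaus after jumps and refuses otherwise", {
  # noiseless step at index k
  s <- c(rep(0, 10), rep(5, 15))
  expect_identical(detectFormation(s), 11L)

  # constant series: no transition
  expect_true(is.na(detectFormation(rep(2, 30))))

  # seeded sigmoid with noise: recovered within the window
  set.seed(5)
  n <- 100
  mid <- 50
  sig <- 5 / (1 + exp(-2 * (seq_len(n) - mid))) + rnorm(n, 0, 0.05)
  got <- detectFormation(sig)
  w <- max(2L, round(0.05 * n))
  expect_false(is.na(got))
  expect_lte(abs(got - mid), w + 2)

  expect_error(detectFormation(c(1, 2, 3), window = 2), "shorter")
})

test_that("cluster identification follows the Ca-P contact graph", {
  pairFrame <- makeFrame(matrix(c(0, 0, 0), 1),
                         list(list(pos = c(2.9, 0, 0), nH = 1)))
  cl <- findClusters(pairFrame, cutoff = 3.5)
  expect_length(cl, 1L)
  expect_identical(unname(composition(cl[[1]])[c("nCa", "nP")]), c(1L, 1L))
  expect_equal(netCharge(cl[[1]]), 0)

  # all ions beyond the cutoff: nothing
  apart <- makeFrame(matrix(c(0, 0, 0), 1),
                     list(list(pos = c(10, 0, 0), nH = 2)))
  expect_length(findClusters(apart, cutoff = 3.5), 0L)

  # planted 4:5 snapshot
  fr <- genClusterSnapshot(clusterSpec(nCa = 4, nHPO4 = 5, waters = 8,
                                       sd = 0.02, seed = 3))
  cl <- findClusters(fr)
  expect_length(cl, 1L)
  expect_identical(unname(composition(cl[[1]])[c("nCa", "nP")]), c(4L, 5L))
  expect_equal(netCharge(cl[[1]]), 2 * 4 - 2 * 5)
})

test_that("cluster detection is invariant to reordering and rigid motion", {
  fr <- genClusterSnapshot(clusterSpec(nCa = 3, nHPO4 = 3, waters = 5,
                                       sd = 0.02, seed = 12))
  base <- findClusters(fr)[[1]]

  set.seed(31)
  a <- atoms(fr)
  perm <- sample(nrow(a))
  shuffled <- atomFrame(a[perm, ], time = frameTime(fr))
  clS <- findClusters(shuffled)
  expect_length(clS, 1L)
  expect_identical(composition(clS[[1]]), composition(base))

  rot <- randomRotation()
  xyz <- as.matrix(a[, c("x", "y", "z")]) %*% t(rot)
  a2 <- a
  a2[, c("x", "y", "z")] <- sweep(xyz, 2, c(12, -3, 7), "+")
  clR <- findClusters(atomFrame(a2))
  expect_identical(composition(clR[[1]]), composition(base))
})

test_that("no ion is lost or double-assigned across clusters and singletons", {
  set.seed(7)
  for (rep in 1:5) {
    nCa <- sample(2:4, 1)
    nP <- sample(2:4, 1)
    ca <- matrix(runif(3 * nCa, 0, 15), nCa)
    ph <- lapply(seq_len(nP), function(i)
      list(pos = runif(3, 0, 15), nH = sample(1:2, 1)))
    fr <- makeFrame(ca, ph)
    cl <- findClusters(fr, cutoff = 4)
    members <- unlist(lapply(cl, function(c) c(c@caAtoms, c@pAtoms)))
    expect_false(any(duplicated(members)))
    sizes <- vapply(cl, function(c) c@nCa + c@nP, integer(1))
    a <- atoms(fr)
    nIons <- sum(a$role %in% c("Ca", "P"))
    expect_lte(sum(sizes), nIons)
    # membership + singletons account for every ion
    d <- pncnmr:::.pairDist(as.matrix(a[a$role == "Ca", c("x", "y", "z")]),
                            as.matrix(a[a$role == "P", c("x", "y", "z")]))
    linked <- sum(apply(d <= 4, 1, any)) + sum(apply(d <= 4, 2, any))
    expect_identical(sum(sizes), as.integer(linked))
  }
})

test_that("hydration counting honours the radius threshold and counts waters once", {
  ca <- matrix(c(0, 0, 0), 1)
  ph <- list(list(pos = c(3, 0, 0), nH = 1))
  waters <- rbind(c(0, 2.5, 0),    # inside 2.7 A
                  c(0, 0, 2.8))    # outside
  fr <- makeFrame(ca, ph, waters)
  cl <- findClusters(fr)[[1]]
  expect_identical(hydrationCount(fr, cl)$count, 1L)

  # a water near two Ca is counted once
  ca2 <- rbind(c(0, 0, 0), c(4, 0, 0))
  ph2 <- list(list(pos = c(2, 2.3, 0), nH = 1))
  wshared <- rbind(c(2, -1.5, 0))  # ~2.5 A from both Ca
  fr2 <- makeFrame(ca2, ph2, wshared)
  cl2 <- findClusters(fr2)[[1]]
  expect_identical(cl2@nCa, 2L)
  expect_identical(hydrationCount(fr2, cl2)$count, 1L)

  # ratio on the 3-Ca fixture
  fr3 <- genClusterSnapshot(clusterSpec(nCa = 3, nHPO4 = 3, waters = 10,
                                        sd = 0))
  cl3 <- findClusters(fr3)[[1]]
  hc <- hydrationCount(fr3, cl3)
  expect_identical(hc$count, 10L)
  expect_equal(hc$ratio, 10 / 3)

  # randomized frames equal the brute-force all-pairs oracle and never
  # exceed the water total
  set.seed(17)
  for (rep in 1:5) {
    fr <- genClusterSnapshot(clusterSpec(nCa = 3, nHPO4 = 3,
                                         waters = sample(4:12, 1),
                                         bulkWaters = 3,
                                         sd = 0.05, seed = rep))
    cl <- findClusters(fr)[[1]]
    hc <- hydrationCount(fr, cl)
    expect_identical(hc$count, bruteHydration(fr, cl))
    expect_lte(hc$count, sum(atoms(fr)$role == "O_W"))
  }
})

test_that("distance histograms normalize, locate modes, and compare to references", {
  # all distances identical: one occupied bin, one mode
  fr <- makeFrame(matrix(c(0, 0, 0), 1),
                  list(list(pos = c(3, 0, 0), nH = 1)))
  h <- distanceHistogram(list(fr))
  expect_equal(sum(h$density), 1)
  expect_identical(sum(h$counts > 0), 1L)
  expect_length(h$modes, 1L)
  expect_lte(abs(h$modes - 3.0), 0.1)

  # two-shell synthetic cluster: modes within one bin of 3.0 / 3.6
  tr <- genTrajectory(trajectorySpec(nFrames = 40, formationFrame = 6,
                                     seed = 14),
                      clusterSpec(nCa = 4, nHPO4 = 5, waters = 6, sd = 0.05,
                                  seed = 14))
  snaps <- extractSnapshots(tr, 6, n = 30)
  h2 <- distanceHistogram(snaps)
  expect_equal(sum(h2$density), 1)
  expect_true(any(abs(h2$modes - 3.0) <= 0.1))
  expect_true(any(abs(h2$modes - 3.6) <= 0.1))

  refs <- compareToCrystalRefs(h2, list(brushite = 3.0, OCP = c(3.0, 3.6)))
  expect_true(all(refs$deviation <= 0.1))
  exact <- compareToCrystalRefs(h2, list(phase = h2$modes[1]))
  expect_equal(exact$deviation, 0)
  expect_error(compareToCrystalRefs(h2, list()), "non-empty")

  expect_error(distanceHistogram(list(fr), range = c(10, 12)), "no Ca-P")
})

test_that("snapshot extraction is evenly spaced and strictly post-formation", {
  cs <- clusterSpec(nCa = 2, nHPO4 = 2, waters = 3, sd = 0.02, seed = 5)
  tr <- genTrajectory(trajectorySpec(nFrames = 40, formationFrame = 5,
                                     seed = 5), cs)
  snaps <- extractSnapshots(tr, 5, n = 7)
  idx <- attr(snaps, "indices")
  expect_length(snaps, 7L)
  expect_true(all(idx > 5))
  expect_identical(length(unique(diff(idx))), 1L)  # constant stride

  all35 <- extractSnapshots(tr, 5, n = 35)
  expect_identical(attr(all35, "indices"), 6:40)
  expect_true(all(vapply(all35, function(f)
    length(findClusters(f)) == 1L, logical(1))))

  expect_error(extractSnapshots(tr, 5, n = 36), "post-formation")
})
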