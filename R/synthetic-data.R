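## Synthetic-data generators.  These stand in for the MD/DFT stages of the
## real study: they emit pseudo-trajectories with a planted calcium
## phosphate cluster, sets of shielding tensors with a known isotropic
## mean, and the transcribed experiment/computation fixture tables.  Every
## generator is a pure function of (spec, seed), and the planted ground
## truth travels with the output so downstream analytics can be tested as
## recovery problems.

P_O_BOND <- 1.54   # P-O bond length, Angstrom
O_H_BOND <- 0.98   # O-H bond length, Angstrom
WATER_CA_DIST <- 2.55  # hydration-water O placement distance from Ca, Angstrom

#' Specification of a planted calcium phosphate cluster
#'
#' Geometry follows the two-shell contact motif of early-stage clusters:
#' every phosphate P sits at the first-shell distance (default 3.0 A) from
#' at least one Ca.  One phosphate per adjacent Ca pair bridges both Ca at
#' the first-shell distance (so the contact graph is connected at any
#' cutoff just above it); the remaining phosphates sit at the first-shell
#' distance from one Ca and the second-shell distance (default 3.6 A)
#' from the adjacent Ca.  Phosphates are full tetrahedral
#' units (P-O 1.54 A) carrying one acidic H (HPO4^2-); hydration waters
#' are placed with their O within the 0.27 nm counting radius of a Ca.
#'
#' @param nCa,nHPO4 member ion counts (each >= 1).
#' @param firstShell,secondShell planted Ca-P contact distances, Angstrom.
#' @param sd Gaussian positional noise applied to every coordinate,
#'   Angstrom (>= 0).
#' @param waters number of hydration waters placed in the first shell.
#' @param bulkWaters additional waters placed far outside the counting
#'   radius.
#' @param seed RNG seed (used only when `sd > 0` for snapshots).
#' @return a list of class `clusterSpec`.
#' @export
clusterSpec <- function(nCa = 3, nHPO4 = 3, firstShell = 3.0,
                        secondShell = 3.6, sd = 0.05, waters = 10,
                        bulkWaters = 0, seed = 1) {
  nCa <- .assertCount(nCa, "nCa", min = 1L)
  nHPO4 <- .assertCount(nHPO4, "nHPO4", min = 1L)
  .assertScalarFinite(firstShell, "firstShell")
  .assertScalarFinite(secondShell, "secondShell")
  if (firstShell <= 0 || secondShell <= 0) stop("shell distances must be > 0")
  .assertScalarFinite(sd, "sd")
  if (sd < 0) stop("sd must be >= 0")
  waters <- .assertCount(waters, "waters")
  bulkWaters <- .assertCount(bulkWaters, "bulkWaters")
  structure(list(nCa = nCa, nHPO4 = nHPO4, firstShell = firstShell,
                 secondShell = secondShell, sd = sd, waters = waters,
                 bulkWaters = bulkWaters, seed = as.integer(seed)),
            class = "clusterSpec")
}

#' Specification of a synthetic ion trajectory
#'
#' @param nFrames number of frames.
#' @param frameInterval time between frames, ns.
#' @param formationFrame 1-based index of the first frame in which the
#'   planted cluster exists; earlier frames hold only dispersed ions.
#' @param boxEdge cubic box edge, nm.
#' @param nFreeH2PO4 diprotonated phosphates that stay dispersed in every
#'   frame (they never join the cluster, mirroring the observation that
#'   only HPO4^2- species cluster).
#' @param seed RNG seed.
#' @return a list of class `trajectorySpec`.
#' @export
trajectorySpec <- function(nFrames = 60, frameInterval = 10,
                           formationFrame = 21, boxEdge = 10,
                           nFreeH2PO4 = 2, seed = 1) {
  nFrames <- .assertCount(nFrames, "nFrames", min = 2L)
  formationFrame <- .assertCount(formationFrame, "formationFrame", min = 1L)
  if (formationFrame > nFrames)
    stop("formationFrame must lie within the trajectory")
  .assertScalarFinite(boxEdge, "boxEdge")
  if (boxEdge <= 0) stop("boxEdge must be positive")
  nFreeH2PO4 <- .assertCount(nFreeH2PO4, "nFreeH2PO4")
  structure(list(nFrames = nFrames, frameInterval = frameInterval,
                 formationFrame = formationFrame, boxEdge = boxEdge,
                 nFreeH2PO4 = nFreeH2PO4, seed = as.integer(seed)),
            class = "trajectorySpec")
}

#' Specification of a synthetic shielding-tensor set
#'
#' @param n number of snapshots (default 35, one per independent ab initio
#'   trajectory in the emulated workflow).
#' @param mean true isotropic shielding mean, ppm.
#' @param sd spread of the isotropic parts across snapshots, ppm.
#' @param anisotropy scale of the symmetric traceless component, ppm
#'   (does not affect the isotropic part).
#' @param seed RNG seed.
#' @return a list of class `shieldingSetSpec`.
#' @export
shieldingSetSpec <- function(n = 35, mean = 281.1, sd = 1,
                             anisotropy = 5, seed = 1) {
  n <- .assertCount(n, "n", min = 2L)
  .assertScalarFinite(mean, "mean")
  .assertScalarFinite(sd, "sd")
  if (sd < 0) stop("sd must be >= 0")
  .assertScalarFinite(anisotropy, "anisotropy")
  if (anisotropy < 0) stop("anisotropy must be >= 0")
  structure(list(n = n, mean = mean, sd = sd, anisotropy = anisotropy,
                 seed = as.integer(seed)),
            class = "shieldingSetSpec")
}

## ---- cluster geometry -----------------------------------------------

## Tetrahedral unit vectors with the first vertex along u1.
.tetrahedron <- function(u1) {
  u1 <- u1 / sqrt(sum(u1^2))
  p1 <- .perpUnit(u1)
  p2 <- c(u1[2] * p1[3] - u1[3] * p1[2],
          u1[3] * p1[1] - u1[1] * p1[3],
          u1[1] * p1[2] - u1[2] * p1[1])
  ang <- c(0, 2, 4) * pi / 3
  rbind(u1, t(vapply(ang, function(t)
    -u1 / 3 + sqrt(8) / 3 * (cos(t) * p1 + sin(t) * p2), numeric(3))))
}

## Atoms of one phosphate unit: P at `pos`, four O tetrahedral, `nH`
## acidic protons extended along the P-O directions.  `u1` orients the
## first O (kept pointing away from the cluster axis to avoid clashes).
.phosphateAtoms <- function(pos, u1, nH, mol) {
  v <- .tetrahedron(u1)
  o <- sweep(v * P_O_BOND, 2, pos, "+")
  at <- data.frame(element = c("P", rep("O", 4)),
                   role = c("P", rep("O_P", 4)),
                   x = c(pos[1], o[, 1]), y = c(pos[2], o[, 2]),
                   z = c(pos[3], o[, 3]), mol = mol)
  if (nH > 0) {
    hIdx <- seq_len(nH)
    h <- sweep(v[hIdx, , drop = FALSE] * (P_O_BOND + O_H_BOND), 2, pos, "+")
    at <- rbind(at, data.frame(element = "H", role = "H_P",
                               x = h[, 1], y = h[, 2], z = h[, 3],
                               mol = mol))
  }
  at
}

## Atoms of one water: O at `pos`, two H fanned away from direction `d`.
.waterAtoms <- function(pos, d, mol) {
  p <- .perpUnit(d)
  h1 <- pos + 0.96 * (0.6 * d + 0.8 * p)
  h2 <- pos + 0.96 * (0.6 * d - 0.8 * p)
  data.frame(element = c("O", "H", "H"), role = c("O_W", "H_W", "H_W"),
             x = c(pos[1], h1[1], h2[1]), y = c(pos[2], h1[2], h2[2]),
             z = c(pos[3], h1[3], h2[3]), mol = mol)
}

## Noise-free cluster template: Ca ions on a line, each phosphate at
## firstShell from one Ca and secondShell from the adjacent Ca (rotated
## about the Ca axis when several phosphates share a Ca pair), hydration
## waters greedily placed on a deterministic direction lattice around the
## Ca ions.  Returns list(atoms, center).
.clusterTemplate <- function(spec) {
  d1 <- spec$firstShell
  d2 <- spec$secondShell
  nCa <- spec$nCa
  nP <- spec$nHPO4

  caPos <- NULL
  pPos <- list()
  pDir <- list()
  if (nCa >= 2L) {
    a <- (d1 + d2) / 2 + 0.7  # Ca-Ca spacing; must admit both shells
    if (a <= abs(d2 - d1) + 0.05 || a >= d1 + d2 - 0.05)
      stop("shell distances geometrically infeasible for the Ca spacing")
    caPos <- cbind((seq_len(nCa) - 1) * a, 0, 0)
    ## backbone phosphates (slot 0) bridge both adjacent Ca at the
    ## first-shell distance, keeping the contact graph connected at any
    ## cutoff just above d1; additional phosphates take the mixed
    ## first/second-shell motif (d1 to one Ca, d2 to the other)
    xlSym <- a / 2
    r2Sym <- d1^2 - xlSym^2
    xlMix <- (a^2 + d1^2 - d2^2) / (2 * a)
    r2Mix <- d1^2 - xlMix^2
    if (r2Sym <= 0.25 || r2Mix <= 0.25)
      stop("shell distances geometrically infeasible")
    nPairs <- nCa - 1L
    maxPerPair <- 4L  # 90 deg slots keep tetrahedral O atoms apart
    for (j in seq_len(nP)) {
      pair <- (j - 1L) %% nPairs + 1L
      slot <- (j - 1L) %/% nPairs
      if (slot >= maxPerPair)
        stop("cannot place ", nP, " phosphates on ", nPairs,
             " Ca pairs without steric overlap")
      phi <- slot * pi / 2 + (pair - 1L) * pi / 4
      radial <- c(0, cos(phi), sin(phi))
      xl <- if (slot == 0L) xlSym else xlMix
      r <- sqrt(if (slot == 0L) r2Sym else r2Mix)
      pPos[[j]] <- c((pair - 1L) * a + xl, r * radial[2], r * radial[3])
      pDir[[j]] <- radial
    }
  } else {
    caPos <- matrix(c(0, 0, 0), 1)
    dirs <- .fibonacciSphere(max(nP, 4L))
    for (j in seq_len(nP)) {
      pPos[[j]] <- d1 * dirs[j, ]
      pDir[[j]] <- dirs[j, ]
    }
  }

  molId <- 0L
  parts <- list()
  for (i in seq_len(nCa)) {
    molId <- molId + 1L
    parts[[length(parts) + 1L]] <-
      data.frame(element = "Ca", role = "Ca", x = caPos[i, 1],
                 y = caPos[i, 2], z = caPos[i, 3], mol = molId)
  }
  for (j in seq_len(nP)) {
    molId <- molId + 1L
    parts[[length(parts) + 1L]] <-
      .phosphateAtoms(pPos[[j]], pDir[[j]], nH = 1L, mol = molId)
  }
  atomsSoFar <- do.call(rbind, parts)

  ## hydration waters: round-robin over Ca ions, deterministic direction
  ## lattice, greedy steric acceptance
  dirs <- .fibonacciSphere(60)
  used <- matrix(FALSE, nCa, nrow(dirs))
  placed <- 0L
  caTurn <- 0L
  tries <- 0L
  while (placed < spec$waters) {
    caTurn <- caTurn %% nCa + 1L
    iDir <- which(!used[caTurn, ])
    ok <- FALSE
    for (k in iDir) {
      o <- caPos[caTurn, ] + WATER_CA_DIST * dirs[k, ]
      dmin <- min(.pairDist(matrix(o, 1),
                            as.matrix(atomsSoFar[, c("x", "y", "z")])))
      if (dmin >= 1.8) {
        used[caTurn, k] <- TRUE
        molId <- molId + 1L
        atomsSoFar <- rbind(atomsSoFar, .waterAtoms(o, dirs[k, ], molId))
        placed <- placed + 1L
        ok <- TRUE
        break
      }
    }
    if (!ok) {
      tries <- tries + 1L
      if (tries > nCa)
        stop("cannot place ", spec$waters,
             " hydration waters without steric overlap")
    } else tries <- 0L
  }

  ## bulk waters: far outside the counting radius of any Ca
  if (spec$bulkWaters > 0L) {
    far <- .fibonacciSphere(spec$bulkWaters)
    ext <- max(.pairDist(colMeans(caPos),
                         as.matrix(atomsSoFar[, c("x", "y", "z")]))) + 8
    for (j in seq_len(spec$bulkWaters)) {
      molId <- molId + 1L
      o <- colMeans(caPos) + ext * far[j, ]
      atomsSoFar <- rbind(atomsSoFar, .waterAtoms(o, far[j, ], molId))
    }
  }
  rownames(atomsSoFar) <- NULL
  list(atoms = atomsSoFar, center = colMeans(caPos))
}

## Minimum distance between atoms of different molecules; the steric
## feasibility criterion for generated frames.
.minInterMolDist <- function(atoms) {
  xyz <- as.matrix(atoms[, c("x", "y", "z")])
  d <- .pairDist(xyz, xyz)
  same <- outer(atoms$mol, atoms$mol, "==")
  diag(same) <- TRUE
  if (all(same)) return(Inf)
  min(d[!same])
}

#' Generate a single cluster snapshot
#'
#' Builds one frame containing the planted cluster of `spec` plus its
#' hydration waters, with optional Gaussian positional noise.  With
#' `sd = 0` every phosphate sits exactly at the planted first-shell
#' distance from its anchor Ca (non-backbone phosphates additionally at
#' the second-shell distance from the adjacent Ca), and the
#' hydration-water count equals `spec$waters` exactly.
#'
#' @param spec a [clusterSpec()].
#' @return an [AtomFrame-class] (non-periodic, t = 0).
#' @examples
#' fr <- genClusterSnapshot(clusterSpec(nCa = 3, nHPO4 = 3, waters = 10,
#'                                      sd = 0))
#' @export
genClusterSnapshot <- function(spec) {
  stopifnot(inherits(spec, "clusterSpec"))
  tpl <- .clusterTemplate(spec)
  atoms <- tpl$atoms
  if (.minInterMolDist(atoms) < 1.0)
    stop("steric overlap below 1 A in generated cluster")
  if (spec$sd > 0) {
    atoms <- withSeed(spec$seed, {
      n <- nrow(atoms)
      atoms$x <- atoms$x + stats::rnorm(n, 0, spec$sd)
      atoms$y <- atoms$y + stats::rnorm(n, 0, spec$sd)
      atoms$z <- atoms$z + stats::rnorm(n, 0, spec$sd)
      atoms
    })
  }
  atomFrame(atoms, box = NA_real_, time = 0)
}

## Rejection-sample `n` points in a cube [margin, edge-margin]^3 with
## pairwise separation >= minSep and (optionally) >= keepOut from `center`.
.scatterPoints <- function(n, edge, minSep, margin = 3,
                           center = NULL, keepOut = 0) {
  if (n == 0L) return(matrix(numeric(), 0, 3))
  if ((edge - 2 * margin)^3 < n * minSep^3 * 2)
    stop("box too small for the requested ion count")
  pts <- matrix(NA_real_, n, 3)
  placed <- 0L
  for (it in seq_len(20000L)) {
    cand <- margin + stats::runif(3) * (edge - 2 * margin)
    okC <- is.null(center) ||
      sqrt(sum((cand - center)^2)) >= keepOut
    okP <- placed == 0L ||
      min(.pairDist(matrix(cand, 1), pts[seq_len(placed), , drop = FALSE])) >=
        minSep
    if (okC && okP) {
      placed <- placed + 1L
      pts[placed, ] <- cand
      if (placed == n) return(pts)
    }
  }
  stop("box too small for the requested ion count")
}

#' Generate a synthetic ion trajectory with a planted formation event
#'
#' Frames before `formationFrame` hold all ions dispersed (pairwise ion
#' separations > 6 A, no clusters at any sensible contact cutoff); frames
#' at and after it embed the planted cluster of `cspec` (plus its
#' hydration waters) with per-frame Gaussian jitter of `cspec$sd`.
#' Diprotonated phosphates (`nFreeH2PO4`) stay dispersed in every frame.
#' Atom ordering is identical across frames.
#'
#' @param tspec a [trajectorySpec()].
#' @param cspec a [clusterSpec()].
#' @return an [IonTrajectory-class]; `groundTruth()` carries the planted
#'   formation frame, composition, hydration count and shell distances.
#' @export
genTrajectory <- function(tspec, cspec) {
  stopifnot(inherits(tspec, "trajectorySpec"), inherits(cspec, "clusterSpec"))
  edge <- tspec$boxEdge * 10  # Angstrom
  tpl <- .clusterTemplate(cspec)
  clusterAtoms <- tpl$atoms
  clusterExtent <- max(.pairDist(matrix(tpl$center, 1),
                                 as.matrix(clusterAtoms[, c("x", "y", "z")])))
  if (2 * clusterExtent + 12 > edge)
    stop("box too small for the requested ion count")

  molMax <- max(clusterAtoms$mol)
  freeParts <- list()
  for (j in seq_len(tspec$nFreeH2PO4)) {
    molMax <- molMax + 1L
    freeParts[[j]] <- .phosphateAtoms(c(0, 0, 0), c(0, 0, 1), nH = 2L,
                                      mol = molMax)
  }
  freeAtoms <- if (length(freeParts)) do.call(rbind, freeParts) else NULL

  ## per-molecule bookkeeping for the dispersed layout
  mols <- clusterAtoms
  if (!is.null(freeAtoms)) mols <- rbind(mols, freeAtoms)
  molIds <- unique(mols$mol)
  ionMols <- molIds[vapply(molIds, function(m)
    any(mols$role[mols$mol == m] %in% c("Ca", "P")), logical(1))]
  waterMols <- setdiff(molIds, ionMols)

  withSeed(tspec$seed, {
    center <- rep(edge / 2, 3)
    ## dispersed ion-centre layout (> 6 A pairwise; kept clear of the
    ## cluster site so post-formation frames stay well separated)
    ionPos <- .scatterPoints(length(ionMols), edge, minSep = 6.5,
                             center = center,
                             keepOut = clusterExtent + 7)
    watPos <- if (length(waterMols))
      .scatterPoints(length(waterMols), edge, minSep = 3,
                     center = center, keepOut = clusterExtent + 7)
    else matrix(numeric(), 0, 3)

    ## reference coordinates per regime, same atom order
    offset <- center - tpl$center
    clusteredRef <- mols
    pre <- mols
    for (k in seq_along(ionMols)) {
      m <- ionMols[k]
      rows <- which(mols$mol == m)
      anchor <- rows[mols$role[rows] %in% c("Ca", "P")][1]
      shift <- ionPos[k, ] - as.numeric(mols[anchor, c("x", "y", "z")])
      pre[rows, c("x", "y", "z")] <-
        sweep(mols[rows, c("x", "y", "z")], 2, shift, "+")
    }
    for (k in seq_along(waterMols)) {
      m <- waterMols[k]
      rows <- which(mols$mol == m)
      shift <- watPos[k, ] - as.numeric(mols[rows[1], c("x", "y", "z")])
      pre[rows, c("x", "y", "z")] <-
        sweep(mols[rows, c("x", "y", "z")], 2, shift, "+")
    }
    ## clustered regime: cluster molecules at the box centre, free
    ## phosphates and any dispersed waters keep their scattered positions
    clusterMols <- unique(clusterAtoms$mol)
    for (m in molIds) {
      rows <- which(mols$mol == m)
      if (m %in% clusterMols) {
        clusteredRef[rows, c("x", "y", "z")] <-
          sweep(mols[rows, c("x", "y", "z")], 2, offset, "+")
      } else {
        clusteredRef[rows, c("x", "y", "z")] <- pre[rows, c("x", "y", "z")]
      }
    }

    frames <- vector("list", tspec$nFrames)
    for (i in seq_len(tspec$nFrames)) {
      base <- if (i >= tspec$formationFrame) clusteredRef else pre
      at <- base
      if (cspec$sd > 0) {
        n <- nrow(at)
        at$x <- at$x + stats::rnorm(n, 0, cspec$sd)
        at$y <- at$y + stats::rnorm(n, 0, cspec$sd)
        at$z <- at$z + stats::rnorm(n, 0, cspec$sd)
      }
      frames[[i]] <- atomFrame(at, box = tspec$boxEdge,
                               time = (i - 1) * tspec$frameInterval)
    }
    ionTrajectory(frames, groundTruth = list(
      formationFrame = tspec$formationFrame,
      nCa = cspec$nCa, nHPO4 = cspec$nHPO4,
      nFreeH2PO4 = tspec$nFreeH2PO4,
      hydrationWaters = cspec$waters,
      firstShell = cspec$firstShell, secondShell = cspec$secondShell))
  })
}

#' Generate a set of synthetic shielding tensors
#'
#' Each tensor is `iso_i * I + anisotropy * A_i` with `iso_i` drawn from
#' `Normal(mean, sd)` and `A_i` a random symmetric traceless matrix, so the
#' isotropic part of tensor i is exactly `iso_i` regardless of the
#' anisotropy scale.
#'
#' @param spec a [shieldingSetSpec()].
#' @return a [ShieldingSet-class]; `@truth` records the planted mean/sd.
#' @export
genShieldingSet <- function(spec) {
  stopifnot(inherits(spec, "shieldingSetSpec"))
  withSeed(spec$seed, {
    iso <- stats::rnorm(spec$n, spec$mean, spec$sd)
    tens <- array(0, c(spec$n, 3, 3))
    for (i in seq_len(spec$n)) {
      a <- matrix(stats::rnorm(9), 3, 3)
      s <- (a + t(a)) / 2
      s <- s - diag(sum(diag(s)) / 3, 3)
      tens[i, , ] <- diag(iso[i], 3) + spec$anisotropy * s
    }
    new("ShieldingSet", tensors = tens,
        snapshot = sprintf("snap%03d", seq_len(spec$n)),
        site = rep("P1", spec$n),
        truth = list(mean = spec$mean, sd = spec$sd,
                     anisotropy = spec$anisotropy))
  })
}

#' Transcribed per-pH shift and shielding fixture tables
#'
#' Returns the experimental 31P observables (shift delta and linewidth
#' Gamma for free and cluster-bound phosphate at pH 6/7/8) and the
#' computed ensemble-averaged shieldings/shifts for the same conditions,
#' as shipped in `inst/extdata`.
#'
#' @return list with data.frames `experimental` (columns `pH`, `deltaPi`,
#'   `deltaPNC`, `dDelta`, `gammaPi`, `gammaPNC`, `dGamma` plus `*Err`) and
#'   `computed` (columns `pH`, `sigmaPi`, `sigmaPNC`, `deltaPi`,
#'   `deltaPNC` plus `*Err`).
#' @export
phosphateShiftTables <- function() {
  p1 <- system.file("extdata", "experimental_31p_shifts.csv",
                    package = "pncnmr", mustWork = TRUE)
  p2 <- system.file("extdata", "computed_31p_shieldings.csv",
                    package = "pncnmr", mustWork = TRUE)
  list(experimental = utils::read.csv(p1), computed = utils::read.csv(p2))
}

#' @rdname phosphateShiftTables
#' @param table one of the two data.frames from [phosphateShiftTables()].
#' @param pH pH key; errors if no such row exists.
#' @export
lookupShiftRow <- function(table, pH) {
  hit <- which(table$pH == pH)
  if (length(hit) != 1L)
    stop("no fixture row for pH = ", pH)
  table[hit, , drop = FALSE]
}

#' @rdname phosphateShiftTables
#' @details `assembleShiftTable()` reshapes the two fixtures into the long
#'   per-(pH, species) table consumed by [correlateShifts()] and
#'   [trendCheck()], pairing each measured shift with its computed
#'   counterpart.
#' @export
assembleShiftTable <- function() {
  tabs <- phosphateShiftTables()
  e <- tabs$experimental
  c2 <- tabs$computed
  stopifnot(identical(e$pH, c2$pH))
  long <- rbind(
    data.frame(pH = e$pH, species = "Pi",
               measured = e$deltaPi, measuredErr = e$deltaPiErr,
               computed = c2$deltaPi, computedErr = c2$deltaPiErr),
    data.frame(pH = e$pH, species = "PNC",
               measured = e$deltaPNC, measuredErr = e$deltaPNCErr,
               computed = c2$deltaPNC, computedErr = c2$deltaPNCErr))
  if (anyDuplicated(long[, c("pH", "species")]))
    stop("duplicate (pH, species) keys in fixture tables")
  long
}
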