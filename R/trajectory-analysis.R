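## Structural analytics of ion trajectories: Ca-P distance RMSD and
## formation detection, connected-component cluster identification,
## hydration-shell counting, pooled distance distributions and their
## comparison against crystal-phase reference distances.

## All Ca-P pair distances of a frame as a vector (row-major over Ca),
## minimum-image when the frame is periodic.
.caPDistances <- function(frame) {
  ca <- .roleXYZ(frame, "Ca")
  p <- .roleXYZ(frame, "P")
  if (nrow(ca) == 0L || nrow(p) == 0L)
    stop("frame must contain Ca and P ions")
  as.vector(.pairDist(ca, p, frame@box))
}

#' RMSD of all Ca-P pair distances between a frame and a reference
#'
#' The displacement measure used to monitor cluster formation: the root
#' mean square deviation of every Ca-P pair distance from its value in the
#' reference frame (typically the starting configuration).  It is zero for
#' identical internal geometry and insensitive to rigid-body motion.
#'
#' @param frame,reference [AtomFrame-class] objects with identical atom
#'   ordering and counts.
#' @return RMSD in Angstrom.
#' @export
rmsdCaP <- function(frame, reference) {
  a <- frame@atoms
  b <- reference@atoms
  if (nrow(a) != nrow(b) || !identical(a$role, b$role) ||
      !identical(a$element, b$element))
    stop("frame and reference must share atom ordering and counts")
  d1 <- .caPDistances(frame)
  d0 <- .caPDistances(reference)
  sqrt(mean((d1 - d0)^2))
}

#' @rdname rmsdCaP
#' @param traj an [IonTrajectory-class].
#' @param referenceFrame index of the reference frame (default 1, the
#'   starting configuration).
#' @return `rmsdSeries()`: numeric vector, one RMSD per frame.
#' @export
rmsdSeries <- function(traj, referenceFrame = 1L) {
  ref <- getFrame(traj, referenceFrame)
  vapply(traj@frames, rmsdCaP, numeric(1), reference = ref)
}

#' Detect the completion of cluster formation in an RMSD series
#'
#' Finds the first index after which the series stays within a plateau
#' band: the earliest `k >= 2` such that the whole tail `series[k:n]`
#' spans no more than `tolerance` while the preceding part of the series
#' departs from that plateau by more than the band (i.e. a jump happened).
#' Returns `NA` with attribute `reason = "not formed"` when no such
#' plateau following a jump exists (e.g. a constant or still-drifting
#' series).
#'
#' @param series numeric RMSD per frame, Angstrom.
#' @param window sliding-window length used for the minimum usable series
#'   length and the reported localization tolerance; default 5% of the
#'   series (at least 2).
#' @param tolerance plateau band width, Angstrom; default 10% of the
#'   series range.
#' @return integer index of the first plateau frame, or `NA_integer_`.
#' @export
detectFormation <- function(series, window = max(2L, round(0.05 * length(series))),
                            tolerance = 0.1 * diff(range(series))) {
  if (!is.numeric(series) || !all(is.finite(series)))
    stop("series must be finite numeric")
  n <- length(series)
  if (n < 2L * window)
    stop("series shorter than twice the window")
  ## running max/min of the tail, right to left
  tmax <- rev(cummax(rev(series)))
  tmin <- rev(cummin(rev(series)))
  plateau <- (tmax - tmin) <= tolerance
  k <- which(plateau)[1]
  if (is.na(k) || k < 2L)
    return(structure(NA_integer_, reason = "not formed"))
  ## require a genuine jump: the pre-plateau part must leave the band
  band <- range(series[k:n])
  before <- series[seq_len(k - 1L)]
  if (!any(before < band[1] - tolerance | before > band[2] + tolerance))
    return(structure(NA_integer_, reason = "not formed"))
  as.integer(k)
}

#' Identify ion clusters as connected components of the Ca-P contact graph
#'
#' Nodes are the Ca and P ions of the frame; edges join Ca-P pairs within
#' `cutoff` (minimum-image when periodic).  Connected components with at
#' least two members are returned with their composition, per-phosphate
#' protonation split, and net charge `2 nCa - 2 nHPO4 - nH2PO4`.
#' Singleton ions are excluded.
#'
#' @param frame an [AtomFrame-class].
#' @param cutoff Ca-P contact distance, Angstrom.  The default 3.5 A sits
#'   just beyond the second-shell contact feature.
#' @return list of [IonCluster-class] objects (possibly empty).
#' @export
findClusters <- function(frame, cutoff = 3.5) {
  .assertScalarFinite(cutoff, "cutoff")
  if (cutoff <= 0) stop("cutoff must be positive")
  caIdx <- .roleIdx(frame, "Ca")
  pIdx <- .roleIdx(frame, "P")
  nodes <- c(caIdx, pIdx)
  if (length(nodes) < 2L) return(list())
  ca <- .roleXYZ(frame, "Ca")
  p <- .roleXYZ(frame, "P")
  d <- .pairDist(ca, p, frame@box)
  hit <- which(d <= cutoff, arr.ind = TRUE)
  g <- igraph::make_empty_graph(n = length(nodes), directed = FALSE)
  if (nrow(hit) > 0) {
    edges <- rbind(hit[, 1], nrow(ca) + hit[, 2])
    g <- igraph::add_edges(g, as.vector(edges))
  }
  comp <- igraph::components(g)
  protons <- .phosphateProtons(frame)  # parallel to pIdx
  out <- list()
  for (ci in seq_len(comp$no)) {
    members <- which(comp$membership == ci)
    if (length(members) < 2L) next
    caM <- members[members <= nrow(ca)]
    pM <- members[members > nrow(ca)] - nrow(ca)
    nHPO4 <- sum(protons[pM] == 1L)
    nH2PO4 <- sum(protons[pM] == 2L)
    out[[length(out) + 1L]] <- new("IonCluster",
      caAtoms = caIdx[caM], pAtoms = pIdx[pM],
      nCa = length(caM), nP = length(pM),
      nHPO4 = as.integer(nHPO4), nH2PO4 = as.integer(nH2PO4),
      charge = 2 * length(caM) - 2 * nHPO4 - nH2PO4,
      boundWaters = NA_integer_)
  }
  ## largest first, for convenience
  if (length(out) > 1L) {
    sz <- vapply(out, function(cl) cl@nCa + cl@nP, integer(1))
    out <- out[order(sz, decreasing = TRUE)]
  }
  out
}

#' Count hydration waters bound to a cluster
#'
#' A water is bound when its O atom lies within `radius` of at least one
#' member Ca ion; each water is counted once even if it neighbours several
#' Ca.  Also reports the water-per-Ca molar ratio, the hydration
#' descriptor of early-stage clusters.
#'
#' @param frame an [AtomFrame-class].
#' @param cluster an [IonCluster-class] from [findClusters()].
#' @param radius counting radius around each Ca, in nm (default 0.27).
#' @return list with `count`, `ratio` (= count / nCa) and the updated
#'   `cluster` carrying `boundWaters`.
#' @export
hydrationCount <- function(frame, cluster, radius = 0.27) {
  .assertScalarFinite(radius, "radius")
  if (radius <= 0) stop("radius must be positive")
  if (cluster@nCa == 0L) stop("cluster has no Ca ions")
  radA <- radius * 10
  a <- frame@atoms
  caXYZ <- as.matrix(a[cluster@caAtoms, c("x", "y", "z"), drop = FALSE])
  ow <- which(a$role == "O_W")
  if (length(ow) == 0L) {
    cluster@boundWaters <- 0L
    return(list(count = 0L, ratio = 0, cluster = cluster))
  }
  d <- .pairDist(as.matrix(a[ow, c("x", "y", "z")]), caXYZ, frame@box)
  nearMol <- unique(a$mol[ow[apply(d <= radA, 1, any)]])
  count <- length(nearMol)
  cluster@boundWaters <- as.integer(count)
  list(count = as.integer(count), ratio = count / cluster@nCa,
       cluster = cluster)
}

#' Pooled Ca-P distance histogram over frames
#'
#' Pools Ca-P distances over the supplied frames, restricted (when
#' `memberships` is given) to cluster-member P centres against all Ca ions
#' -- the convention that treats the P atom as the centre of gravity of
#' its phosphate.  Densities are normalized to sum to one over the bins;
#' modes are local maxima of a 3-bin moving average of the density.
#'
#' @param frames list of [AtomFrame-class] objects (or an
#'   [IonTrajectory-class]).
#' @param memberships optional list of [IonCluster-class] objects parallel
#'   to `frames`; when given, only member P atoms contribute.
#' @param binWidth bin width in Angstrom (default 0.1).
#' @param range distance window in Angstrom (default `c(2, 6)`).
#' @return list of class `distanceHistogram`: `breaks`, `mid`, `counts`,
#'   `density`, `modes` (Angstrom).
#' @export
distanceHistogram <- function(frames, memberships = NULL, binWidth = 0.1,
                              range = c(2, 6)) {
  if (is(frames, "IonTrajectory")) frames <- frames@frames
  if (length(frames) < 1L) stop("at least one frame required")
  .assertScalarFinite(binWidth, "binWidth")
  if (binWidth <= 0) stop("binWidth must be positive")
  pool <- numeric()
  for (i in seq_along(frames)) {
    fr <- frames[[i]]
    ca <- .roleXYZ(fr, "Ca")
    if (is.null(memberships)) {
      p <- .roleXYZ(fr, "P")
    } else {
      cl <- memberships[[i]]
      p <- as.matrix(fr@atoms[cl@pAtoms, c("x", "y", "z"), drop = FALSE])
    }
    if (nrow(ca) && nrow(p))
      pool <- c(pool, as.vector(.pairDist(ca, p, fr@box)))
  }
  pool <- pool[pool >= range[1] & pool <= range[2]]
  if (length(pool) == 0L) stop("no Ca-P distances in the requested range")
  breaks <- seq(range[1], range[2] + binWidth * 0.5, by = binWidth)
  counts <- as.vector(table(cut(pool, breaks = breaks,
                                include.lowest = TRUE, right = FALSE)))
  dens <- counts / sum(counts)
  mid <- breaks[-length(breaks)] + binWidth / 2
  ## modes: local maxima of the 3-bin moving average; runs of equal
  ## smoothed density count as one plateau, located at the raw-density
  ## peak inside the run
  sm <- stats::filter(dens, rep(1 / 3, 3), sides = 2)
  sm[is.na(sm)] <- 0
  sm <- as.numeric(sm)
  runs <- rle(sm)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  modes <- numeric()
  for (r in seq_along(runs$values)) {
    v <- runs$values[r]
    if (v <= 0) next
    left <- if (r > 1) runs$values[r - 1] else -Inf
    right <- if (r < length(runs$values)) runs$values[r + 1] else -Inf
    if (v > left && v > right) {
      span <- starts[r]:ends[r]
      modes <- c(modes, mid[span[which.max(dens[span])]])
    }
  }
  structure(list(breaks = breaks, mid = mid, counts = counts,
                 density = dens, modes = modes),
            class = "distanceHistogram")
}

#' @export
print.distanceHistogram <- function(x, ...) {
  cat(sprintf("Ca-P distance histogram: %d distances in [%g, %g] A, bin %g A\n",
              sum(x$counts), min(x$breaks), max(x$breaks),
              diff(x$breaks[1:2])))
  cat("  modes (A):", paste(sprintf("%.2f", x$modes), collapse = ", "), "\n")
  invisible(x)
}

#' Extract evenly spaced post-formation snapshots
#'
#' Selects `n` frames strictly after the formation frame at a constant
#' stride (the largest integer stride that fits), the sampling used to
#' seed per-snapshot quantum calculations.
#'
#' @param traj an [IonTrajectory-class].
#' @param formationFrame index of the formation frame; snapshots start
#'   after it.
#' @param n number of snapshots (default 35).
#' @return list of [AtomFrame-class] objects, with the chosen frame
#'   indices as attribute `indices`.
#' @export
extractSnapshots <- function(traj, formationFrame, n = 35L) {
  n <- .assertCount(n, "n", min = 1L)
  formationFrame <- .assertCount(formationFrame, "formationFrame", min = 0L)
  avail <- seq(formationFrame + 1L, length.out =
                 max(0L, nFrames(traj) - formationFrame))
  if (length(avail) < n)
    stop("only ", length(avail), " post-formation frames for n = ", n)
  stride <- length(avail) %/% n
  idx <- avail[stride * seq_len(n)]
  structure(traj@frames[idx], indices = idx)
}

#' Compare histogram modes to crystal-phase reference distances
#'
#' For every reference Ca-P distance of each crystal phase (e.g. brushite,
#' octacalcium phosphate, hydroxyapatite), reports the absolute deviation
#' to the nearest histogram mode.  Reference distances are user-supplied;
#' no defaults are assumed.
#'
#' @param hist a `distanceHistogram` from [distanceHistogram()].
#' @param references named list: phase -> numeric reference distances, A.
#' @return data.frame with columns `phase`, `reference`, `nearestMode`,
#'   `deviation` (Angstrom).
#' @export
compareToCrystalRefs <- function(hist, references) {
  stopifnot(inherits(hist, "distanceHistogram"))
  if (!is.list(references) || length(references) == 0L ||
      is.null(names(references)) || any(names(references) == ""))
    stop("references must be a non-empty named list of distances")
  if (length(hist$modes) == 0L) stop("histogram has no modes")
  rows <- lapply(names(references), function(ph) {
    ref <- references[[ph]]
    near <- vapply(ref, function(r) hist$modes[which.min(abs(hist$modes - r))],
                   numeric(1))
    data.frame(phase = ph, reference = ref, nearestMode = near,
               deviation = abs(near - ref))
  })
  do.call(rbind, rows)
}
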