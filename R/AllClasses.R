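#' @import methods
NULL

## Closed role vocabulary for atoms in a frame.  "Ca" and "P" are the ion
## centres all cluster analytics operate on; phosphate O/H and water O/H are
## distinguished so hydration counting and protonation bookkeeping never
## depend on element symbols alone.
.ROLES <- c("Ca", "P", "O_P", "H_P", "O_W", "H_W", "ion")

#' AtomFrame: one timestamped frame of atomic coordinates
#'
#' A single snapshot of an ion/water system.  Atoms carry an element symbol,
#' a role from the closed vocabulary (`Ca`, `P`, phosphate `O_P`/`H_P`,
#' water `O_W`/`H_W`, or generic `ion`), Cartesian coordinates in Angstrom,
#' and a molecule id grouping atoms that belong to the same phosphate unit
#' or water molecule.
#'
#' @slot atoms data.frame with columns `element`, `role`, `x`, `y`, `z`
#'   (Angstrom) and `mol` (integer molecule id).
#' @slot box numeric(1); cubic box edge length in Angstrom, or `NA_real_`
#'   for a non-periodic frame.  Distances use the minimum-image convention
#'   when a box is present.
#' @slot time numeric(1); timestamp in nanoseconds.
#'
#' @seealso [atomFrame()], [findClusters()], [rmsdCaP()]
#' @export
setClass("AtomFrame",
  representation(atoms = "data.frame", box = "numeric", time = "numeric"),
  prototype(atoms = data.frame(element = character(), role = character(),
                               x = numeric(), y = numeric(), z = numeric(),
                               mol = integer()),
            box = NA_real_, time = 0))

setValidity("AtomFrame", function(object) {
  a <- object@atoms
  need <- c("element", "role", "x", "y", "z", "mol")
  if (!all(need %in% names(a)))
    return(sprintf("atoms must have columns %s", paste(need, collapse = ", ")))
  if (!all(a$role %in% .ROLES))
    return(sprintf("unknown role(s): %s",
                   paste(unique(setdiff(a$role, .ROLES)), collapse = ", ")))
  xyz <- as.matrix(a[, c("x", "y", "z")])
  if (nrow(a) > 0L && !all(is.finite(xyz)))
    return("coordinates must be finite")
  if (length(object@box) != 1L)
    return("box must be a single edge length (Angstrom) or NA")
  if (!is.na(object@box) && object@box <= 0)
    return("box edge must be positive")
  TRUE
})

#' IonTrajectory: an ordered series of frames
#'
#' Frames share one atom ordering so per-atom quantities are comparable
#' across time.  Synthetic trajectories carry their construction ground
#' truth (planted formation frame, composition, hydration count) in
#' `groundTruth`, giving every downstream analytic a recovery oracle.
#'
#' @slot frames list of [AtomFrame-class] objects.
#' @slot groundTruth list; planted truth for generated data (may be empty).
#'
#' @export
setClass("IonTrajectory",
  representation(frames = "list", groundTruth = "list"),
  prototype(frames = list(), groundTruth = list()))

setValidity("IonTrajectory", function(object) {
  if (!all(vapply(object@frames, is, logical(1), class2 = "AtomFrame")))
    return("all frames must be AtomFrame objects")
  if (length(object@frames) > 1L) {
    n <- vapply(object@frames, function(f) nrow(f@atoms), integer(1))
    if (length(unique(n)) != 1L)
      return("all frames must contain the same number of atoms")
  }
  TRUE
})

#' ShieldingSet: per-snapshot 3x3 magnetic shielding tensors
#'
#' Holds one symmetric 3x3 shielding tensor (ppm) per snapshot/site, the
#' raw material for bootstrap ensemble averaging.  Generated sets carry the
#' true isotropic mean in `truth`.
#'
#' @slot tensors numeric array `n x 3 x 3` in ppm.
#' @slot snapshot character; snapshot identifiers (length n).
#' @slot site character; site identifiers (length n).
#' @slot truth list; planted ground truth for synthetic sets (may be empty).
#'
#' @export
setClass("ShieldingSet",
  representation(tensors = "array", snapshot = "character",
                 site = "character", truth = "list"),
  prototype(tensors = array(numeric(), c(0, 3, 3)),
            snapshot = character(), site = character(), truth = list()))

setValidity("ShieldingSet", function(object) {
  d <- dim(object@tensors)
  if (length(d) != 3L || d[2] != 3L || d[3] != 3L)
    return("tensors must be an n x 3 x 3 array")
  if (length(object@snapshot) != d[1] || length(object@site) != d[1])
    return("snapshot and site ids must match the number of tensors")
  if (d[1] > 0L && !all(is.finite(object@tensors)))
    return("tensor components must be finite")
  TRUE
})

#' EnsembleResult: bootstrap ensemble average of isotropic shieldings
#'
#' Output of [bootstrapAverage()]: the recorded per-iteration bootstrap
#' means, their running cumulative mean (for convergence checks), the final
#' ensemble average taken over the last `finalWindow` iterations, the
#' empirical 95% percentile confidence interval and the derived uncertainty
#' `Err = (CI_0.975 - CI_0.025) / (2 z)` with `z = 1.96`.
#'
#' @slot values numeric; input isotropic shieldings, ppm.
#' @slot bootMeans numeric; one resampled mean per iteration, ppm.
#' @slot cumMean numeric; running cumulative mean of `bootMeans`, ppm.
#' @slot mean numeric(1); final ensemble average, ppm.
#' @slot ci numeric(2); empirical 2.5% and 97.5% percentiles, ppm.
#' @slot err numeric(1); CI half-width divided by the z-score, ppm.
#' @slot z numeric(1); z-score used (1.96).
#' @slot finalWindow integer(1); number of trailing iterations averaged.
#' @slot seed integer(1); RNG seed used for resampling.
#'
#' @export
setClass("EnsembleResult",
  representation(values = "numeric", bootMeans = "numeric",
                 cumMean = "numeric", mean = "numeric", ci = "numeric",
                 err = "numeric", z = "numeric", finalWindow = "integer",
                 seed = "integer"))

setValidity("EnsembleResult", function(object) {
  if (length(object@ci) != 2L || object@ci[1] > object@ci[2])
    return("ci must be (lower, upper) with lower <= upper")
  if (object@err < 0) return("err must be non-negative")
  if (length(object@bootMeans) != length(object@cumMean))
    return("cumMean must parallel bootMeans")
  TRUE
})

#' IonCluster: a connected Ca/phosphate ion cluster
#'
#' One connected component of the Ca-P contact graph at the configured
#' distance cutoff, with composition, protonation and charge bookkeeping.
#'
#' @slot caAtoms integer; atom-row indices of member Ca ions.
#' @slot pAtoms integer; atom-row indices of member P centres.
#' @slot nCa integer(1); number of Ca2+ ions.
#' @slot nP integer(1); number of phosphate units.
#' @slot nHPO4 integer(1); members in the monoprotonated state.
#' @slot nH2PO4 integer(1); members in the diprotonated state.
#' @slot charge numeric(1); net charge in elementary units,
#'   `2 nCa - 2 nHPO4 - nH2PO4`.
#' @slot boundWaters integer(1); hydration waters (NA until counted).
#'
#' @export
setClass("IonCluster",
  representation(caAtoms = "integer", pAtoms = "integer", nCa = "integer",
                 nP = "integer", nHPO4 = "integer", nH2PO4 = "integer",
                 charge = "numeric", boundWaters = "integer"),
  prototype(boundWaters = NA_integer_))

setValidity("IonCluster", function(object) {
  if (object@nCa + object@nP < 2L)
    return("a cluster needs at least two member ions")
  if (object@nHPO4 + object@nH2PO4 != object@nP)
    return("protonation states must account for every phosphate")
  TRUE
})

#' Spectrum1D: a one-dimensional NMR spectrum
#'
#' Intensities on a uniform chemical-shift grid, together with the
#' spectrometer frequency needed to convert linewidths between ppm/ppb
#' and Hz.
#'
#' @slot ppm numeric; strictly monotone chemical-shift axis, ppm.
#' @slot intensity numeric; intensities (arbitrary units).
#' @slot freqMHz numeric(1); spectrometer carrier frequency, MHz.
#'
#' @export
setClass("Spectrum1D",
  representation(ppm = "numeric", intensity = "numeric", freqMHz = "numeric"))

setValidity("Spectrum1D", function(object) {
  if (length(object@ppm) != length(object@intensity))
    return("axis and intensities must have equal length")
  d <- diff(object@ppm)
  if (length(d) && !(all(d > 0) || all(d < 0)))
    return("chemical-shift axis must be strictly monotone")
  if (!all(is.finite(object@intensity)))
    return("intensities must be finite")
  if (object@freqMHz <= 0) return("spectrometer frequency must be positive")
  TRUE
})

#' ReferenceCalibration: shielding-to-shift referencing
#'
#' Captures the reference shielding `sigmaRef = sigmaObs + deltaObs` so
#' that `delta = sigmaRef - sigma` reproduces the observed shift of the
#' calibration sample exactly (shift and shielding run with opposite sign).
#'
#' @slot sigmaRef numeric(1); reference shielding, ppm.
#' @slot deltaObs numeric(1); observed shift of the calibration sample, ppm.
#' @slot sigmaObs numeric(1); computed shielding of the same sample, ppm.
#'
#' @export
setClass("ReferenceCalibration",
  representation(sigmaRef = "numeric", deltaObs = "numeric",
                 sigmaObs = "numeric"))

setValidity("ReferenceCalibration", function(object) {
  ok <- is.finite(object@sigmaRef) && is.finite(object@deltaObs) &&
    is.finite(object@sigmaObs)
  if (!ok) return("calibration values must be finite")
  if (abs((object@sigmaRef - object@sigmaObs) - object@deltaObs) > 1e-9)
    return("sigmaRef must equal sigmaObs + deltaObs")
  TRUE
})
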