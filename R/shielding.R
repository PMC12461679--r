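## Bootstrap ensemble averaging of isotropic magnetic shieldings, with
## percentile confidence intervals, convergence tracking, speciation
## weighting across phosphate protonation states, and shielding-to-shift
## referencing.

#' @rdname isotropicShielding
#' @export
setMethod("isotropicShielding", "matrix", function(x) {
  if (!all(dim(x) == c(3L, 3L))) stop("tensor must be 3x3")
  if (!all(is.finite(x))) stop("tensor components must be finite")
  mean(diag(x))
})

#' @rdname isotropicShielding
#' @export
setMethod("isotropicShielding", "ShieldingSet", function(x) {
  n <- dim(x@tensors)[1]
  vapply(seq_len(n), function(i) mean(diag(x@tensors[i, , ])), numeric(1))
})

#' Bootstrap ensemble average of isotropic shieldings
#'
#' Runs `nIter` bootstrap iterations: each draws `length(values)` samples
#' with replacement and records the arithmetic mean.  The final ensemble
#' average is the mean of the last `finalWindow` recorded iterations
#' (default the last 15, i.e. iterations 986-1000 of a 1000-iteration
#' run); `useAll = TRUE` averages all iterations instead.  The running
#' cumulative mean of the bootstrap means is retained so convergence can
#' be inspected, and the 95% confidence interval is taken as empirical
#' percentiles (linear interpolation) of the bootstrap means, giving
#' `Err = (CI_0.975 - CI_0.025) / (2 z)` with `z = 1.96`.
#'
#' When `values` is a [ShieldingSet-class], multiple sites sharing a
#' snapshot id are averaged per snapshot first, so resampling operates on
#' one value per snapshot.
#'
#' @param values numeric isotropic shieldings (ppm), or a
#'   [ShieldingSet-class].
#' @param nIter number of bootstrap iterations (default 1000).
#' @param seed RNG seed for the resampling.
#' @param finalWindow trailing iterations averaged for the final value.
#' @param useAll average all iterations instead of the trailing window.
#' @return an [EnsembleResult-class].
#' @examples
#' r <- bootstrapAverage(rnorm(35, 281, 1), seed = 7)
#' ensembleMean(r); bootstrapError(r)
#' @export
bootstrapAverage <- function(values, nIter = 1000L, seed = 1L,
                             finalWindow = 15L, useAll = FALSE) {
  if (is(values, "ShieldingSet")) {
    iso <- isotropicShielding(values)
    values <- as.numeric(tapply(iso, values@snapshot, mean))
  }
  if (!is.numeric(values) || length(values) < 2L)
    stop("need at least 2 shielding values")
  if (!all(is.finite(values))) stop("shielding values must be finite")
  nIter <- .assertCount(nIter, "nIter", min = 2L)
  finalWindow <- .assertCount(finalWindow, "finalWindow", min = 1L)
  if (finalWindow > nIter) stop("finalWindow cannot exceed nIter")
  n <- length(values)
  bootMeans <- withSeed(seed, {
    vapply(seq_len(nIter), function(i)
      mean(values[sample.int(n, n, replace = TRUE)]), numeric(1))
  })
  sel <- if (useAll) seq_len(nIter) else (nIter - finalWindow + 1L):nIter
  ci <- unname(stats::quantile(bootMeans, c(0.025, 0.975), type = 7))
  new("EnsembleResult",
      values = as.numeric(values), bootMeans = bootMeans,
      cumMean = cumsum(bootMeans) / seq_len(nIter),
      mean = mean(bootMeans[sel]), ci = ci,
      err = (ci[2] - ci[1]) / (2 * 1.96), z = 1.96,
      finalWindow = if (useAll) as.integer(nIter) else finalWindow,
      seed = as.integer(seed))
}

#' @rdname bootstrapAverage
#' @param x an [EnsembleResult-class].
#' @export
setMethod("ensembleMean", "EnsembleResult", function(x) x@mean)

#' @rdname bootstrapAverage
#' @details `bootstrapError()` returns `Err`, the 95% CI half-width in
#'   z-score units; it is 0 (not an error) for a degenerate constant
#'   input.
#' @export
setMethod("bootstrapError", "EnsembleResult", function(x) x@err)

setMethod("show", "EnsembleResult", function(object) {
  cat(sprintf("EnsembleResult: <sigma_iso> = %.4f ppm (Err = %.4f ppm)\n",
              object@mean, object@err))
  cat(sprintf("  n = %d values, %d bootstrap iterations, final window %d, CI95 [%.4f, %.4f]\n",
              length(object@values), length(object@bootMeans),
              object@finalWindow, object@ci[1], object@ci[2]))
})

#' Check convergence of the bootstrap running mean
#'
#' The running cumulative mean of the bootstrap means should stabilize
#' well within the uncertainty: the range of its last `tail` values is
#' compared against `Err`.
#'
#' @param result an [EnsembleResult-class].
#' @param tail number of trailing cumulative-mean values inspected.
#' @return list with `converged` (logical), `tailRange` and `err` (ppm).
#' @export
convergenceCheck <- function(result, tail = 100L) {
  stopifnot(is(result, "EnsembleResult"))
  tail <- .assertCount(tail, "tail", min = 2L)
  cm <- result@cumMean
  tr <- diff(range(utils::tail(cm, tail)))
  list(converged = tr <= max(result@err, .Machine$double.eps),
       tailRange = tr, err = result@err)
}

#' Speciation-weighted average shielding
#'
#' Convex combination of the ensemble shieldings of the two phosphate
#' protonation states, weighted by their Henderson-Hasselbalch mole
#' fractions: the H2PO4^- fraction multiplies the H2PO4^- shielding and
#' the HPO4^2- fraction the HPO4^2- shielding.  The weights argument is
#' the named vector from [speciationFraction()], which makes the pairing
#' explicit; a bare scalar is interpreted as the H2PO4^- fraction.
#'
#' @param sigmaH2PO4,sigmaHPO4 ensemble shieldings of the two species, ppm.
#' @param weights named vector from [speciationFraction()], or the
#'   H2PO4^- mole fraction as a scalar in `[0, 1]`.
#' @return weighted average shielding, ppm; always between the two inputs.
#' @export
weightedAverage <- function(sigmaH2PO4, sigmaHPO4, weights) {
  .assertScalarFinite(sigmaH2PO4, "sigmaH2PO4")
  .assertScalarFinite(sigmaHPO4, "sigmaHPO4")
  chi <- if (length(weights) > 1L) {
    if (is.null(names(weights)) || !"H2PO4" %in% names(weights))
      stop("weights must name the H2PO4 fraction (see speciationFraction)")
    unname(weights[["H2PO4"]])
  } else as.numeric(weights)
  if (!is.finite(chi) || chi < 0 || chi > 1)
    stop("weight must lie in [0, 1]")
  chi * sigmaH2PO4 + (1 - chi) * sigmaHPO4
}

#' Calibrate the shielding-to-shift reference
#'
#' From one calibration pair (an observed shift `deltaObs` and the
#' computed shielding `sigmaObs` of the same sample), fixes
#' `sigmaRef = sigmaObs + deltaObs` so that `shieldingToShift(sigmaObs)`
#' returns `deltaObs` exactly.
#'
#' @param deltaObs observed chemical shift of the calibration sample, ppm.
#' @param sigmaObs computed isotropic shielding of the same sample, ppm.
#' @return a [ReferenceCalibration-class].
#' @examples
#' cal <- calibrateReference(deltaObs = 0.04, sigmaObs = 281.1)
#' cal@sigmaRef             # 281.14
#' shieldingToShift(281.1, cal)  # 0.04
#' @export
calibrateReference <- function(deltaObs, sigmaObs) {
  .assertScalarFinite(deltaObs, "deltaObs")
  .assertScalarFinite(sigmaObs, "sigmaObs")
  new("ReferenceCalibration", sigmaRef = sigmaObs + deltaObs,
      deltaObs = deltaObs, sigmaObs = sigmaObs)
}

setMethod("show", "ReferenceCalibration", function(object) {
  cat(sprintf("ReferenceCalibration: sigma_ref = %.4f ppm (delta %.4f ppm at sigma %.4f ppm)\n",
              object@sigmaRef, object@deltaObs, object@sigmaObs))
})

#' Convert a shielding to a chemical shift
#'
#' `delta = sigmaRef - sigma`: shift and shielding run with opposite
#' signs, so the output is strictly decreasing in the shielding.
#'
#' @param sigma isotropic shielding(s), ppm.
#' @param calibration a [ReferenceCalibration-class].
#' @return chemical shift(s), ppm.
#' @export
shieldingToShift <- function(sigma, calibration) {
  stopifnot(is(calibration, "ReferenceCalibration"))
  if (!all(is.finite(sigma))) stop("sigma must be finite")
  calibration@sigmaRef - sigma
}

## ---- tensor I/O ------------------------------------------------------

#' Read and write shielding tensors as TSV
#'
#' The tabular interchange format has one row per tensor: `snapshot_id`,
#' `site_id`, then the nine components `s11 ... s33` (ppm, row-major).
#'
#' @param path file path.
#' @return `readShieldingTsv()`: a [ShieldingSet-class].
#' @export
readShieldingTsv <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  comp <- c("s11", "s12", "s13", "s21", "s22", "s23", "s31", "s32", "s33")
  if (!all(c("snapshot_id", "site_id", comp) %in% names(df)))
    stop("expected columns snapshot_id, site_id, s11..s33")
  n <- nrow(df)
  tens <- array(0, c(n, 3, 3))
  for (i in seq_len(n))
    tens[i, , ] <- matrix(as.numeric(df[i, comp]), 3, 3, byrow = TRUE)
  new("ShieldingSet", tensors = tens,
      snapshot = as.character(df$snapshot_id),
      site = as.character(df$site_id), truth = list())
}

#' @rdname readShieldingTsv
#' @param x a [ShieldingSet-class].
#' @export
writeShieldingTsv <- function(x, path) {
  stopifnot(is(x, "ShieldingSet"))
  n <- dim(x@tensors)[1]
  m <- t(vapply(seq_len(n), function(i) as.vector(t(x@tensors[i, , ])),
                numeric(9)))
  df <- data.frame(snapshot_id = x@snapshot, site_id = x@site)
  comp <- c("s11", "s12", "s13", "s21", "s22", "s23", "s31", "s32", "s33")
  df[comp] <- as.data.frame(m)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Minimal magres-dialect reader for shielding tensors
#'
#' Parses `ms` records (`ms <label> <index> <s11> ... <s33>`) from the
#' `[magres]` block of a magres-format file; other records are ignored.
#'
#' @param path magres file path.
#' @param label optional atom label filter (e.g. `"P"`).
#' @return a [ShieldingSet-class] with snapshot ids taken from the file
#'   name and site ids `<label><index>`.
#' @export
readMagres <- function(path, label = NULL) {
  lines <- readLines(path, warn = FALSE)
  inBlock <- FALSE
  rows <- list()
  for (ln in lines) {
    t <- trimws(ln)
    if (t == "[magres]") { inBlock <- TRUE; next }
    if (t == "[/magres]") { inBlock <- FALSE; next }
    if (!inBlock) next
    f <- strsplit(t, "\\s+")[[1]]
    if (length(f) >= 12L && f[1] == "ms") {
      if (!is.null(label) && f[2] != label) next
      rows[[length(rows) + 1L]] <-
        list(site = paste0(f[2], f[3]), vals = as.numeric(f[4:12]))
    }
  }
  if (length(rows) == 0L) stop("no ms records found in ", path)
  n <- length(rows)
  tens <- array(0, c(n, 3, 3))
  for (i in seq_len(n))
    tens[i, , ] <- matrix(rows[[i]]$vals, 3, 3, byrow = TRUE)
  new("ShieldingSet", tensors = tens,
      snapshot = rep(basename(path), n),
      site = vapply(rows, `[[`, character(1), "site"), truth = list())
}
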