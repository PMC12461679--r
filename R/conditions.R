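## Solution-condition bookkeeping: phosphate speciation, simulation-box
## electroneutrality, and the mixing/dilution arithmetic of the
## stopped-flow style injection experiments.

#' Phosphate speciation fractions from the Henderson-Hasselbalch relation
#'
#' Mole fractions of the two middle phosphate protonation states
#' (H2PO4^- / HPO4^2-) at a given pH.  The fraction of the deprotonated
#' species is `10^(pH - pKa2) / (1 + 10^(pH - pKa2))`; the two fractions
#' sum to one.  H3PO4 and PO4^3- are neglected, which is accurate between
#' pH 6 and 8 where only the middle species are populated appreciably.
#'
#' Both fractions are returned under explicit names so no ambiguity can
#' arise about which species a weight multiplies (see [weightedAverage()]).
#'
#' @param pH solution pH (dimensionless).
#' @param pKa2 second acid dissociation constant of phosphoric acid;
#'   default 7.2, the literature value near 25 C.
#' @return named numeric vector with components `H2PO4` and `HPO4`,
#'   each in `[0, 1]`, summing to 1.
#' @examples
#' speciationFraction(7.2)        # 0.5 / 0.5 at the equivalence point
#' speciationFraction(4.5)[["HPO4"]]  # ~0.002: almost pure H2PO4^-
#' @export
speciationFraction <- function(pH, pKa2 = 7.2) {
  .assertScalarFinite(pH, "pH")
  .assertScalarFinite(pKa2, "pKa2")
  r <- 10^(pH - pKa2)
  hpo4 <- r / (1 + r)
  if (!is.finite(hpo4)) hpo4 <- 1  # r overflowed: fully deprotonated
  c(H2PO4 = 1 - hpo4, HPO4 = hpo4)
}

#' Electroneutral simulation-box composition
#'
#' Given the ion inventory of a simulation box (Ca2+, Cl-, and the two
#' phosphate protonation states at the pH-appropriate split), returns the
#' number of K+ counter-ions required for exact electroneutrality:
#' `nK = nCl + 2 nHPO4 + nH2PO4 - 2 nCa`.  Errors if the required K+
#' count would be negative (over-cationic inventory).
#'
#' @param nHPO4,nH2PO4 phosphate counts in the two protonation states.
#' @param nCa number of Ca2+ ions (default 4).
#' @param nCl number of Cl- ions (default 8).
#' @param nWater number of water molecules carried through unchanged.
#' @return list with the six species counts (`nCa`, `nCl`, `nK`, `nHPO4`,
#'   `nH2PO4`, `nWater`) and the verified `netCharge` (always 0).
#' @examples
#' composeBox(nHPO4 = 2, nH2PO4 = 6)$nK  # 10
#' composeBox(nHPO4 = 4, nH2PO4 = 4)$nK  # 12
#' @export
composeBox <- function(nHPO4, nH2PO4, nCa = 4, nCl = 8, nWater = 0) {
  nHPO4 <- .assertCount(nHPO4, "nHPO4")
  nH2PO4 <- .assertCount(nH2PO4, "nH2PO4")
  nCa <- .assertCount(nCa, "nCa")
  nCl <- .assertCount(nCl, "nCl")
  nWater <- .assertCount(nWater, "nWater")
  nK <- nCl + 2L * nHPO4 + nH2PO4 - 2L * nCa
  if (nK < 0L)
    stop("over-cationic inventory: electroneutrality would require ",
         -nK, " fewer positive charges (negative K+ count)")
  charge <- 2L * nCa + nK - nCl - 2L * nHPO4 - nH2PO4
  stopifnot(charge == 0L)
  list(nCa = nCa, nCl = nCl, nK = nK, nHPO4 = nHPO4, nH2PO4 = nH2PO4,
       nWater = nWater, netCharge = charge)
}

#' Mixing/dilution arithmetic for the injection experiment
#'
#' Final concentrations after injecting one solution into a prefilled NMR
#' tube, by conservation of moles: `c_final = c V / (V_prefill + V_inject)`
#' for each solute.  Also reports the ionic product `[Ca][Pi]` (mM^2) and
#' the ratio `[Ca]/[Pi]` of the two final concentrations.
#'
#' With `asPrinted = TRUE` the final concentrations are first rounded to
#' `digits` decimals before the product and ratio are formed, reproducing
#' numbers quoted from rounded concentrations (e.g. 6.7 x 12.8 = 85.76);
#' the default reports full precision.
#'
#' @param prefillVolume,injectVolume volumes in uL (both > 0).
#' @param prefillConc concentration of the prefilled solute (e.g. CaCl2),
#'   mM.
#' @param injectConc concentration of the injected solute (e.g. phosphate),
#'   mM.
#' @param asPrinted round final concentrations to `digits` decimals before
#'   combining.
#' @param digits decimals used by `asPrinted`.
#' @return list: `finalPrefill` and `finalInject` (mM), `totalVolume` (uL),
#'   `ionicProduct` (mM^2) and `ratio` (prefill/inject).
#' @examples
#' m <- mixingCalculator(150, 20, 300, 19.2, asPrinted = TRUE)
#' m$ionicProduct  # 85.76 mM^2
#' @export
mixingCalculator <- function(prefillVolume, prefillConc,
                             injectVolume, injectConc,
                             asPrinted = FALSE, digits = 1) {
  .assertScalarFinite(prefillVolume, "prefillVolume")
  .assertScalarFinite(injectVolume, "injectVolume")
  .assertScalarFinite(prefillConc, "prefillConc")
  .assertScalarFinite(injectConc, "injectConc")
  if (prefillVolume <= 0 || injectVolume <= 0)
    stop("volumes must be positive")
  if (prefillConc < 0 || injectConc < 0)
    stop("concentrations must be non-negative")
  vTot <- prefillVolume + injectVolume
  cPre <- prefillConc * prefillVolume / vTot
  cInj <- injectConc * injectVolume / vTot
  p <- if (asPrinted) round(cPre, digits) else cPre
  q <- if (asPrinted) round(cInj, digits) else cInj
  list(finalPrefill = cPre, finalInject = cInj, totalVolume = vTot,
       ionicProduct = p * q,
       ratio = if (q == 0) NA_real_ else p / q)
}

#' Read solution conditions from a YAML file
#'
#' Convenience reader for condition files holding any of: `pH`, `pKa2`,
#' `temperatureK`, box counts (`nCa`, `nCl`, `nHPO4`, `nH2PO4`, `nWater`)
#' and mixing entries (`prefillVolume`, `prefillConc`, `injectVolume`,
#' `injectConc`), volumes in uL and concentrations in mM.
#'
#' @param path YAML file path.
#' @return named list of conditions.
#' @export
readConditions <- function(path) {
  cond <- yaml::read_yaml(path)
  if (!is.null(cond$pH) && (cond$pH < 0 || cond$pH > 14))
    stop("pH must lie in [0, 14]")
  num <- intersect(names(cond),
                   c("prefillVolume", "injectVolume", "prefillConc",
                     "injectConc", "nCa", "nCl", "nHPO4", "nH2PO4", "nWater"))
  bad <- num[vapply(num, function(k) any(cond[[k]] < 0), logical(1))]
  if (length(bad))
    stop("negative value for: ", paste(bad, collapse = ", "))
  cond
}
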