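#' Construct an AtomFrame
#'
#' @param atoms data.frame with columns `element`, `role`, `x`, `y`, `z`
#'   (Angstrom) and `mol` (integer molecule id).
#' @param box cubic box edge length in nm (the MD-side convention), or `NA`
#'   for a non-periodic frame.  Stored internally in Angstrom.
#' @param time timestamp in ns.
#' @return an [AtomFrame-class] object.
#' @export
atomFrame <- function(atoms, box = NA_real_, time = 0) {
  atoms$element <- as.character(atoms$element)
  atoms$role <- as.character(atoms$role)
  atoms$mol <- as.integer(atoms$mol)
  rownames(atoms) <- NULL
  new("AtomFrame", atoms = atoms,
      box = if (is.na(box)) NA_real_ else as.numeric(box) * 10,
      time = as.numeric(time))
}

#' @rdname AtomFrame-class
#' @export
setMethod("atoms", "AtomFrame", function(x) x@atoms)

#' @rdname AtomFrame-class
#' @export
setMethod("boxEdge", "AtomFrame", function(x) x@box / 10)  # nm

#' @rdname AtomFrame-class
#' @export
setMethod("frameTime", "AtomFrame", function(x) x@time)

setMethod("show", "AtomFrame", function(object) {
  a <- object@atoms
  cat(sprintf("AtomFrame: %d atoms (t = %.3g ns%s)\n", nrow(a), object@time,
              if (is.na(object@box)) ""
              else sprintf(", box %.3g nm", object@box / 10)))
  tab <- table(factor(a$role, levels = .ROLES))
  cat("  roles:", paste(sprintf("%s=%d", names(tab), tab), collapse = " "),
      "\n")
})

## Coordinate matrix for a role subset, in Angstrom.
.roleXYZ <- function(frame, role) {
  a <- frame@atoms
  as.matrix(a[a$role %in% role, c("x", "y", "z"), drop = FALSE])
}

## Atom-row indices for a role.
.roleIdx <- function(frame, role) which(frame@atoms$role %in% role)

## Number of acidic protons on each phosphate unit, keyed by mol id:
## 1 -> HPO4^2-, 2 -> H2PO4^-.
.phosphateProtons <- function(frame) {
  a <- frame@atoms
  pmol <- a$mol[a$role == "P"]
  vapply(pmol, function(m) sum(a$mol == m & a$role == "H_P"), integer(1))
}

#' @rdname IonTrajectory-class
#' @param frames list of [AtomFrame-class] objects.
#' @param groundTruth list of planted construction truth (may be empty).
#' @export
ionTrajectory <- function(frames, groundTruth = list())
  new("IonTrajectory", frames = frames, groundTruth = groundTruth)

#' @rdname IonTrajectory-class
#' @export
setMethod("nFrames", "IonTrajectory", function(x) length(x@frames))

#' @rdname IonTrajectory-class
#' @param i frame index.
#' @export
setMethod("getFrame", "IonTrajectory", function(x, i) {
  i <- .assertCount(i, "frame index", min = 1L)
  if (i > length(x@frames)) stop("frame index out of range")
  x@frames[[i]]
})

#' @rdname IonTrajectory-class
#' @export
setMethod("groundTruth", "IonTrajectory", function(x) x@groundTruth)

setMethod("show", "IonTrajectory", function(object) {
  n <- length(object@frames)
  cat(sprintf("IonTrajectory: %d frames", n))
  if (n > 0) {
    t0 <- object@frames[[1]]@time
    t1 <- object@frames[[n]]@time
    cat(sprintf(" (%.3g-%.3g ns)", t0, t1))
  }
  if (!is.null(object@groundTruth$formationFrame))
    cat(sprintf(", planted formation at frame %d",
                object@groundTruth$formationFrame))
  cat("\n")
})

setMethod("show", "IonCluster", function(object) {
  cat(sprintf("IonCluster: %d Ca : %d P (%d HPO4^2-, %d H2PO4^-), charge %+g e",
              object@nCa, object@nP, object@nHPO4, object@nH2PO4,
              object@charge))
  if (!is.na(object@boundWaters))
    cat(sprintf(", %d bound waters", object@boundWaters))
  cat("\n")
})

#' @rdname findClusters
#' @export
setMethod("composition", "IonCluster", function(x)
  c(nCa = x@nCa, nP = x@nP, nHPO4 = x@nHPO4, nH2PO4 = x@nH2PO4))

#' @rdname findClusters
#' @export
setMethod("netCharge", "IonCluster", function(x) x@charge)
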