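#' @rdname AtomFrame-class
#' @param object,x an object.
#' @export
setGeneric("atoms", function(x) standardGeneric("atoms"))

#' @rdname AtomFrame-class
#' @export
setGeneric("boxEdge", function(x) standardGeneric("boxEdge"))

#' @rdname AtomFrame-class
#' @export
setGeneric("frameTime", function(x) standardGeneric("frameTime"))

#' @rdname IonTrajectory-class
#' @export
setGeneric("nFrames", function(x) standardGeneric("nFrames"))

#' @rdname IonTrajectory-class
#' @export
setGeneric("getFrame", function(x, i) standardGeneric("getFrame"))

#' @rdname IonTrajectory-class
#' @export
setGeneric("groundTruth", function(x) standardGeneric("groundTruth"))

#' Isotropic part of a magnetic shielding tensor
#'
#' The isotropic shielding is the mean of the three diagonal components
#' (one third of the trace); it is invariant under rotation of the
#' molecular frame.
#'
#' @param x a 3x3 numeric matrix, or a [ShieldingSet-class] (one value per
#'   tensor).
#' @return numeric; isotropic shielding(s) in ppm.
#' @examples
#' isotropicShielding(diag(c(280, 281, 282)))  # 281
#' @export
setGeneric("isotropicShielding", function(x) standardGeneric("isotropicShielding"))

#' @rdname bootstrapAverage
#' @export
setGeneric("ensembleMean", function(x) standardGeneric("ensembleMean"))

#' @rdname bootstrapAverage
#' @export
setGeneric("bootstrapError", function(x) standardGeneric("bootstrapError"))

#' @rdname findClusters
#' @export
setGeneric("composition", function(x) standardGeneric("composition"))

#' @rdname findClusters
#' @export
setGeneric("netCharge", function(x) standardGeneric("netCharge"))
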