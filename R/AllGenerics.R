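#' Accessors for Profile1D
#'
#' @param x a [Profile1D-class] object.
#' @return `qValues` and `intensityValues` return numeric vectors;
#'   `sigmaValues` returns a numeric vector or NULL; `profileMeta` a list.
#' @name profile-accessors
NULL

#' @rdname profile-accessors
#' @export
setGeneric("qValues", function(x) standardGeneric("qValues"))
#' @rdname profile-accessors
#' @export
setGeneric("intensityValues",
           function(x) standardGeneric("intensityValues"))
#' @rdname profile-accessors
#' @export
setGeneric("sigmaValues", function(x) standardGeneric("sigmaValues"))
#' @rdname profile-accessors
#' @export
setGeneric("profileMeta", function(x) standardGeneric("profileMeta"))

#' @rdname profile-accessors
setMethod("qValues", "Profile1D", function(x) x@q)
#' @rdname profile-accessors
setMethod("intensityValues", "Profile1D", function(x) x@intensity)
#' @rdname profile-accessors
setMethod("sigmaValues", "Profile1D",
          function(x) if (length(x@sigma)) x@sigma else NULL)
#' @rdname profile-accessors
setMethod("profileMeta", "Profile1D", function(x) x@meta)

#' Accessors for fitted lattice parameters
#'
#' Lattice parameters are reported in nm (the unit of every printed spacing)
#' even though peak positions are handled in inverse Angstrom.
#'
#' @param x a [LatticeFit-class] object.
#' @return a numeric scalar (NA when the parameter does not apply to the
#'   phase), a data.frame for `peakAssignments`, or a character scalar for
#'   `phaseName`.
#' @name lattice-accessors
NULL

#' @rdname lattice-accessors
#' @export
setGeneric("latticeD", function(x) standardGeneric("latticeD"))
#' @rdname lattice-accessors
#' @export
setGeneric("latticeC", function(x) standardGeneric("latticeC"))
#' @rdname lattice-accessors
#' @export
setGeneric("latticeA", function(x) standardGeneric("latticeA"))
#' @rdname lattice-accessors
#' @export
setGeneric("rSquared", function(x) standardGeneric("rSquared"))
#' @rdname lattice-accessors
#' @export
setGeneric("peakAssignments", function(x) standardGeneric("peakAssignments"))
#' @rdname lattice-accessors
#' @export
setGeneric("phaseName", function(x) standardGeneric("phaseName"))

#' @rdname lattice-accessors
setMethod("latticeD", "LatticeFit", function(x) x@d)
#' @rdname lattice-accessors
setMethod("latticeC", "LatticeFit", function(x) x@c)
#' @rdname lattice-accessors
setMethod("latticeA", "LatticeFit", function(x) x@a)
#' @rdname lattice-accessors
setMethod("rSquared", "LatticeFit", function(x) x@rSquared)
#' @rdname lattice-accessors
setMethod("peakAssignments", "LatticeFit", function(x) x@assignments)
#' @rdname lattice-accessors
setMethod("phaseName", "LatticeFit", function(x) x@phase)
#' @rdname lattice-accessors
setMethod("phaseName", "PhaseCatalog", function(x) x@phase)

#' Accessors for PeakModel
#'
#' @param x a [PeakModel-class] object.
#' @return numeric scalar (`peakCenter`, `peakWidth`, `peakAmplitude`) or
#'   character scalar (`peakKind`).
#' @name peak-accessors
NULL

#' @rdname peak-accessors
#' @export
setGeneric("peakCenter", function(x) standardGeneric("peakCenter"))
#' @rdname peak-accessors
#' @export
setGeneric("peakWidth", function(x) standardGeneric("peakWidth"))
#' @rdname peak-accessors
#' @export
setGeneric("peakAmplitude", function(x) standardGeneric("peakAmplitude"))
#' @rdname peak-accessors
#' @export
setGeneric("peakKind", function(x) standardGeneric("peakKind"))

#' @rdname peak-accessors
setMethod("peakCenter", "PeakModel", function(x) x@q1)
#' @rdname peak-accessors
setMethod("peakWidth", "PeakModel", function(x) x@h)
#' @rdname peak-accessors
setMethod("peakAmplitude", "PeakModel", function(x) x@amplitude)
#' @rdname peak-accessors
setMethod("peakKind", "PeakModel", function(x) x@kind)

#' Reflections table of a catalog
#'
#' @param x a [PhaseCatalog-class] object.
#' @return data.frame with columns label, h, k, l, modulus.
#' @export
setGeneric("reflections", function(x) standardGeneric("reflections"))
#' @rdname reflections
setMethod("reflections", "PhaseCatalog", function(x) x@reflections)

#' Peptide sequence accessor
#'
#' @param x a [PeptideRecord-class] object.
#' @return character scalar.
#' @export
setGeneric("peptideSequence", function(x) standardGeneric("peptideSequence"))
#' @rdname peptideSequence
setMethod("peptideSequence", "PeptideRecord", function(x) x@sequence)
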