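#' @import methods
NULL

.PHASES <- c("lamellar", "square_columnar", "hexagonal_columnar",
             "tetragonal_columnar", "cubic_pn3m")
.PEAK_KINDS <- c("lorentzian", "squared_lorentzian")

#' Profile1D: a one-dimensional scattering curve
#'
#' Container for a background-corrected or raw 1D SAXS profile: a strictly
#' increasing momentum-transfer grid \code{q} (internally always in inverse
#' Angstrom), intensities in arbitrary units, an optional per-point
#' uncertainty, and free-form provenance metadata (sample name, charge ratio,
#' ...).
#'
#' @slot q numeric, momentum transfer in inverse Angstrom; strictly
#'   increasing, all positive, length >= 2.
#' @slot intensity numeric, same length as \code{q}; may be negative after
#'   background subtraction.
#' @slot sigma numeric, per-point uncertainty; either length 0 (absent) or
#'   the length of \code{q}.
#' @slot meta list of provenance labels.
#'
#' @seealso [readProfile()], [subtractBackground()], [windowProfile()]
#' @export
setClass("Profile1D",
  representation(q = "numeric", intensity = "numeric", sigma = "numeric",
                 meta = "list"),
  prototype(sigma = numeric(0), meta = list()))

setValidity("Profile1D", function(object) {
  msg <- character(0)
  if (length(object@q) < 2L)
    msg <- c(msg, "profile needs at least 2 points")
  if (length(object@q) != length(object@intensity))
    msg <- c(msg, "q and intensity must have equal length")
  if (anyNA(object@q) || any(object@q <= 0))
    msg <- c(msg, "q values must be positive and non-missing")
  if (is.unsorted(object@q, strictly = TRUE))
    msg <- c(msg, "q must be strictly increasing")
  if (length(object@sigma) &&
      length(object@sigma) != length(object@q))
    msg <- c(msg, "sigma must be empty or match the q grid")
  if (length(msg)) msg else TRUE
})

#' Construct a Profile1D
#'
#' @param q momentum transfer grid (inverse Angstrom), strictly increasing.
#' @param intensity scattering intensities (arbitrary units).
#' @param sigma optional per-point uncertainties.
#' @param meta optional named list of provenance labels.
#' @return a [Profile1D-class] object.
#' @examples
#' p <- Profile1D(q = c(0.1, 0.2, 0.3), intensity = c(5, 4, 3))
#' qValues(p)
#' @export
Profile1D <- function(q, intensity, sigma = NULL, meta = list()) {
  new("Profile1D", q = as.numeric(q), intensity = as.numeric(intensity),
      sigma = if (is.null(sigma)) numeric(0) else as.numeric(sigma),
      meta = meta)
}

#' PeakModel: one fitted Bragg peak
#'
#' A single diffraction peak described by a line-shape family, a center
#' \code{q1}, a width parameter \code{h} (with h/2 the half-width scale) and
#' an amplitude multiplying the area-normalized shape. The normalized
#' squared-Lorentzian has center height 4/(pi*h); the normalized Lorentzian
#' 2/(pi*h). Uncertainties, when present, are standard errors from the fit.
#'
#' @slot kind "lorentzian" or "squared_lorentzian".
#' @slot q1 peak center (inverse Angstrom), positive.
#' @slot h width parameter (inverse Angstrom), positive.
#' @slot amplitude positive scale on the normalized shape.
#' @slot centerUncertainty,widthUncertainty standard errors (NA when unknown).
#' @slot converged logical; FALSE marks a best-effort, non-converged fit.
#' @export
setClass("PeakModel",
  representation(kind = "character", q1 = "numeric", h = "numeric",
                 amplitude = "numeric", centerUncertainty = "numeric",
                 widthUncertainty = "numeric", converged = "logical"),
  prototype(centerUncertainty = NA_real_, widthUncertainty = NA_real_,
            converged = TRUE))

setValidity("PeakModel", function(object) {
  msg <- character(0)
  if (!object@kind %in% .PEAK_KINDS)
    msg <- c(msg, sprintf("kind must be one of: %s",
                          paste(.PEAK_KINDS, collapse = ", ")))
  if (!isTRUE(object@h > 0)) msg <- c(msg, "h must be > 0")
  if (!isTRUE(object@q1 > 0)) msg <- c(msg, "q1 must be > 0")
  if (!isTRUE(object@amplitude > 0)) msg <- c(msg, "amplitude must be > 0")
  if (length(msg)) msg else TRUE
})

#' Construct a PeakModel
#'
#' @param kind line-shape family, "lorentzian" or "squared_lorentzian".
#' @param q1 peak center (inverse Angstrom).
#' @param h width parameter (inverse Angstrom).
#' @param amplitude scale on the normalized shape (default 1).
#' @param centerUncertainty,widthUncertainty optional standard errors.
#' @param converged logical convergence flag.
#' @return a [PeakModel-class] object.
#' @examples
#' pk <- PeakModel("squared_lorentzian", q1 = 0.17, h = 0.02)
#' evaluatePeak(pk, 0.17) # = 4/(pi*0.02)
#' @export
PeakModel <- function(kind, q1, h, amplitude = 1,
                      centerUncertainty = NA_real_,
                      widthUncertainty = NA_real_, converged = TRUE) {
  new("PeakModel", kind = kind, q1 = q1, h = h, amplitude = amplitude,
      centerUncertainty = centerUncertainty,
      widthUncertainty = widthUncertainty, converged = converged)
}

#' PhaseCatalog: permitted reflections of a mesophase
#'
#' The ordered list of symmetry-permitted reflections for one mesophase and
#' their dimensionless moduli (the factor multiplying 2*pi/d in the peak
#' position). For the tetragonal columnar phase positions depend on two
#' lattice parameters, so its entries carry the index pair (h^2+k^2, l)
#' and the modulus column is NA.
#'
#' @slot phase one of lamellar, square_columnar, hexagonal_columnar,
#'   tetragonal_columnar, cubic_pn3m.
#' @slot reflections data.frame with columns label, h, k, l, modulus.
#' @slot nParams number of lattice parameters (2 for tetragonal, else 1).
#' @seealso [permittedModuli()]
#' @export
setClass("PhaseCatalog",
  representation(phase = "character", reflections = "data.frame",
                 nParams = "integer"))

setValidity("PhaseCatalog", function(object) {
  msg <- character(0)
  if (!object@phase %in% .PHASES)
    msg <- c(msg, sprintf("phase must be one of: %s",
                          paste(.PHASES, collapse = ", ")))
  need <- c("label", "h", "k", "l", "modulus")
  if (!all(need %in% names(object@reflections)))
    msg <- c(msg, "reflections must have columns label, h, k, l, modulus")
  m <- object@reflections$modulus
  if (object@phase != "tetragonal_columnar" && length(m) &&
      (anyNA(m) || is.unsorted(m, strictly = TRUE)))
    msg <- c(msg, "moduli must be strictly increasing")
  if (length(msg)) msg else TRUE
})

#' LatticeFit: a phase assignment with regressed lattice parameters
#'
#' Result of regressing measured Bragg positions against a reflection
#' catalog. Exactly the parameters appropriate to the phase are set: the
#' in-plane spacing \code{d} (columnar and lamellar phases, nm), the
#' out-of-plane repeat \code{c} (tetragonal only, nm), or the cubic lattice
#' parameter \code{a} (nm). \code{rSquared} is computed in q^2 regression
#' space with the uncentered total sum of squares (the defining lattice
#' equations have no intercept), so it is not comparable to a centered R^2.
#' A "disordered" verdict carries only the first-peak spacing estimate.
#'
#' @slot phase phase name or "disordered".
#' @slot d,c,a lattice parameters in nm (NA when not applicable).
#' @slot rSquared uncentered goodness of fit in q^2 space (<= 1).
#' @slot assignments data.frame: qMeasured, label, h, k, l, qPredicted,
#'   residual, matched.
#' @slot nMatched number of peaks assigned to catalog reflections.
#' @export
setClass("LatticeFit",
  representation(phase = "character", d = "numeric", c = "numeric",
                 a = "numeric", rSquared = "numeric",
                 assignments = "data.frame", nMatched = "integer"),
  prototype(d = NA_real_, c = NA_real_, a = NA_real_, rSquared = NA_real_,
            assignments = data.frame(), nMatched = 0L))

setValidity("LatticeFit", function(object) {
  msg <- character(0)
  ph <- object@phase
  if (!ph %in% c(.PHASES, "disordered"))
    msg <- c(msg, "unknown phase")
  chk <- function(x) length(x) == 1L && (is.na(x) || x > 0)
  if (!chk(object@d) || !chk(object@c) || !chk(object@a))
    msg <- c(msg, "lattice parameters must be positive scalars or NA")
  if (ph == "cubic_pn3m" && is.na(object@a))
    msg <- c(msg, "cubic fit must set a")
  if (ph %in% c("lamellar", "square_columnar", "hexagonal_columnar",
                "tetragonal_columnar", "disordered") && is.na(object@d))
    msg <- c(msg, sprintf("%s fit must set d", ph))
  if (ph == "tetragonal_columnar" && is.na(object@c))
    msg <- c(msg, "tetragonal fit must set c")
  if (ph != "tetragonal_columnar" && !is.na(object@c))
    msg <- c(msg, "c is only defined for the tetragonal phase")
  if (ph != "cubic_pn3m" && !is.na(object@a))
    msg <- c(msg, "a is only defined for the cubic phase")
  if (!is.na(object@rSquared) && object@rSquared > 1 + 1e-12)
    msg <- c(msg, "rSquared must be <= 1")
  if (length(msg)) msg else TRUE
})

#' PeptideRecord: a peptide sequence with residue classifications
#'
#' One-letter amino-acid sequence plus the residue sets counted as cationic,
#' anionic and hydrophobic. The hydrophobic set is a deliberate knob: every
#' report names the set used. The default set \{L, I, V, F, M, W, C\} is the
#' strongly hydrophobic residues (aliphatic beyond alanine, aromatic except
#' tyrosine, cysteine); see the package vignette for why alanine is excluded
#' by default.
#'
#' @slot name identifier.
#' @slot sequence one-letter amino-acid string (20 standard letters).
#' @slot cationicSet,anionicSet,hydrophobicSet character vectors of residue
#'   letters.
#' @export
setClass("PeptideRecord",
  representation(name = "character", sequence = "character",
                 cationicSet = "character", anionicSet = "character",
                 hydrophobicSet = "character"),
  prototype(cationicSet = c("K", "R"), anionicSet = c("D", "E"),
            hydrophobicSet = c("L", "I", "V", "F", "M", "W", "C")))

.AA20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

setValidity("PeptideRecord", function(object) {
  msg <- character(0)
  if (!nzchar(object@sequence))
    msg <- c(msg, "sequence must be non-empty")
  letters1 <- strsplit(object@sequence, "")[[1]]
  bad <- which(!letters1 %in% .AA20)
  if (length(bad))
    msg <- c(msg, sprintf("invalid residue letter '%s' at position %d",
                          letters1[bad[1]], bad[1]))
  if (length(msg)) msg else TRUE
})

#' Construct a PeptideRecord
#'
#' @param name identifier.
#' @param sequence one-letter amino-acid string.
#' @param cationicSet residues counted as positively charged (default K, R).
#' @param anionicSet residues counted as negatively charged (default D, E).
#' @param hydrophobicSet residues counted as hydrophobic (default
#'   L, I, V, F, M, W, C).
#' @return a [PeptideRecord-class] object.
#' @examples
#' mel <- PeptideRecord("melittin", ampPeptides()[["melittin"]])
#' countResidues(mel, "cationic")
#' @export
PeptideRecord <- function(name, sequence,
                          cationicSet = c("K", "R"),
                          anionicSet = c("D", "E"),
                          hydrophobicSet = c("L", "I", "V", "F", "M", "W",
                                             "C")) {
  new("PeptideRecord", name = name, sequence = toupper(sequence),
      cationicSet = cationicSet, anionicSet = anionicSet,
      hydrophobicSet = hydrophobicSet)
}

# ---- show methods ---------------------------------------------------------

setMethod("show", "Profile1D", function(object) {
  cat(sprintf("Profile1D: %d points, q in [%.4g, %.4g] A^-1%s\n",
              length(object@q), min(object@q), max(object@q),
              if (length(object@sigma)) ", with uncertainties" else ""))
  if (length(object@meta)) {
    lab <- paste(names(object@meta), unlist(object@meta, use.names = FALSE),
                 sep = ": ", collapse = "; ")
    cat(" meta:", lab, "\n")
  }
  invisible(object)
})

setMethod("show", "PeakModel", function(object) {
  cat(sprintf(
    "PeakModel (%s): q1 = %.5g A^-1, h = %.4g A^-1, amplitude = %.4g%s\n",
    object@kind, object@q1, object@h, object@amplitude,
    if (!object@converged) " [not converged]" else ""))
  invisible(object)
})

setMethod("show", "PhaseCatalog", function(object) {
  cat(sprintf("PhaseCatalog: %s, %d reflections, %d lattice parameter(s)\n",
              object@phase, nrow(object@reflections), object@nParams))
  print(utils::head(object@reflections, 8))
  if (nrow(object@reflections) > 8) cat(" ...\n")
  invisible(object)
})

setMethod("show", "LatticeFit", function(object) {
  if (object@phase == "disordered") {
    cat(sprintf("LatticeFit: disordered, d = %.3f nm (first-peak estimate)\n",
                object@d))
  } else {
    par <- c(d = object@d, c = object@c, a = object@a)
    par <- par[!is.na(par)]
    cat(sprintf("LatticeFit: %s, %s, R^2 = %.6g, %d peak(s) matched\n",
                object@phase,
                paste(sprintf("%s = %.3f nm", names(par), par),
                      collapse = ", "),
                object@rSquared, object@nMatched))
  }
  invisible(object)
})

setMethod("show", "PeptideRecord", function(object) {
  cat(sprintf("PeptideRecord: %s (%d aa)\n %s\n", object@name,
              nchar(object@sequence), object@sequence))
  invisible(object)
})
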