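# Sequence-level metrics of amphipathic helical peptides: cationic residue
# counts, charge density along a protofibril axis, the matching DNA charge
# density, hydrophobic fraction, and the hydrophobic face angle on an ideal
# helical wheel.

#' Count classified residues in a peptide
#'
#' @param record a [PeptideRecord-class] object.
#' @param which `"cationic"`, `"anionic"` or `"hydrophobic"`; the residue
#'   sets live on the record.
#' @return integer count.
#' @export
countResidues <- function(record, which = c("cationic", "anionic",
                                            "hydrophobic")) {
  stopifnot(is(record, "PeptideRecord"))
  which <- match.arg(which)
  set <- slot(record, paste0(which, "Set"))
  sum(strsplit(record@sequence, "")[[1]] %in% set)
}

#' Protofibril helix geometry
#'
#' A superhelical peptide filament described by the number of monomers per
#' helical turn and the axial rise per monomer; the pitch is their product
#' by construction. The four-fold protofibrils scaffolding DNA columns have
#' 4 monomers per turn with per-monomer rises of 0.82 nm (melittin,
#' 3.28 nm/turn) or 1.7 nm (LL37, 6.8 nm/turn).
#'
#' @param monomersPerTurn monomer count per helical turn.
#' @param risePerMonomer axial rise per monomer (nm), > 0.
#' @return list with monomersPerTurn, risePerMonomer, pitch (nm).
#' @examples
#' protofibrilGeometry(4, 0.82)$pitch # 3.28 nm
#' @export
protofibrilGeometry <- function(monomersPerTurn, risePerMonomer) {
  if (!isTRUE(risePerMonomer > 0)) stop("risePerMonomer must be > 0")
  if (!isTRUE(monomersPerTurn > 0)) stop("monomersPerTurn must be > 0")
  list(monomersPerTurn = monomersPerTurn,
       risePerMonomer = risePerMonomer,
       pitch = monomersPerTurn * risePerMonomer)
}

#' Axial cationic charge density along a protofibril
#'
#' Number of cationic (by default K/R) residues presented per axial window
#' along the filament: cationic count per monomer times the number of
#' monomers per window, window / risePerMonomer.
#'
#' @param record a [PeptideRecord-class] object.
#' @param geometry from [protofibrilGeometry()].
#' @param window axial window in nm (default 3.4, one DNA helical turn of
#'   10 bp).
#' @return list with `density` (charges per window, unrounded) and
#'   `rounded` (nearest integer).
#' @examples
#' mel <- PeptideRecord("melittin", ampPeptides()[["melittin"]])
#' axialChargeDensity(mel, protofibrilGeometry(4, 0.82)) # 20.7 -> 21
#' @export
axialChargeDensity <- function(record, geometry, window = 3.4) {
  stopifnot(is(record, "PeptideRecord"))
  if (!isTRUE(window > 0)) stop("window must be > 0")
  n <- countResidues(record, "cationic")
  density <- n * window / geometry$risePerMonomer
  list(density = density, rounded = round(density))
}

#' Linear charge density of B-form DNA
#'
#' charges_per_bp * window / rise_per_bp: with 2 phosphate charges per base
#' pair and a 0.34 nm rise, one 3.4 nm helical turn carries 20 negative
#' charges.
#'
#' @param risePerBp axial rise per base pair (nm, default 0.34).
#' @param chargesPerBp charges per base pair (default 2).
#' @param window axial window (nm, default 3.4).
#' @return charges per window.
#' @examples
#' dnaChargeDensity() # 20
#' @export
dnaChargeDensity <- function(risePerBp = 0.34, chargesPerBp = 2,
                             window = 3.4) {
  if (!isTRUE(risePerBp > 0)) stop("risePerBp must be > 0")
  chargesPerBp * window / risePerBp
}

#' Hydrophobic residue fraction
#'
#' @param record a [PeptideRecord-class] object.
#' @return hydrophobic count / sequence length.
#' @export
hydrophobicFraction <- function(record) {
  stopifnot(is(record, "PeptideRecord"))
  countResidues(record, "hydrophobic") / nchar(record@sequence)
}

#' Hydrophobic face angle on an ideal helical wheel
#'
#' Places residue i at angle (i-1) * degreesPerResidue (mod 360) on an
#' ideal alpha-helical wheel and returns the smallest wheel sector
#' containing every hydrophobic residue: 360 degrees minus the largest
#' hydrophobic-free gap between consecutive hydrophobic angles. When the
#' largest gap does not exceed the wheel's angular resolution (the gcd of
#' the rotation step and 360, i.e. the residues cover the wheel uniformly)
#' the wheel is considered fully covered and 360 is returned; with no
#' hydrophobic residues the face is 0. Kinked peptides (proline or glycine
#' hinges) are better analyzed per helical segment via `segment`, since a
#' single wheel misrepresents a helix-bend-helix motif.
#'
#' @param record a [PeptideRecord-class] object.
#' @param degreesPerResidue wheel rotation per residue (default 100, the
#'   ideal alpha helix of 3.6 residues/turn).
#' @param segment optional length-2 integer range of residues to analyze
#'   (at least 4 residues).
#' @return face angle in degrees, rounded to the nearest degree.
#' @export
hydrophobicFaceAngle <- function(record, degreesPerResidue = 100,
                                 segment = NULL) {
  stopifnot(is(record, "PeptideRecord"))
  letters1 <- strsplit(record@sequence, "")[[1]]
  idx <- seq_along(letters1)
  if (!is.null(segment)) {
    if (length(segment) != 2L || segment[1] < 1 ||
        segment[2] > length(letters1))
      stop("segment must lie within the sequence")
    if (diff(segment) + 1 < 4)
      stop("segment must span at least 4 residues")
    idx <- segment[1]:segment[2]
  }
  hyd <- idx[letters1[idx] %in% record@hydrophobicSet]
  if (!length(hyd)) return(0)
  ang <- sort(unique(((hyd - idx[1]) * degreesPerResidue) %% 360))
  if (length(ang) == 1L) return(0)
  gaps <- diff(c(ang, ang[1] + 360))
  step <- .wheelStep(degreesPerResidue)
  gmax <- max(gaps)
  if (gmax <= step + 1e-9) return(360)
  round(360 - gmax)
}

# angular resolution of the wheel: gcd of the (rounded) step and 360
.wheelStep <- function(degreesPerResidue) {
  a <- round(degreesPerResidue) %% 360
  if (a == 0) return(360)
  b <- 360
  while (b) { t <- a %% b; a <- b; b <- t }
  a
}

#' Peptide sequences of the studied antimicrobial peptides
#'
#' The six alpha-helical peptides analyzed throughout the package examples:
#' LL37, melittin, buforin and the melittin-derived analogs MM1, AR23 and
#' RV23.
#'
#' @return named character vector of one-letter sequences.
#' @export
ampPeptides <- function() {
  c(LL37 = "LLGDFFRKSKEKIGKEFKRIVQRIKDFLRNLVPRTES",
    melittin = "GIGAVLKVLTTGLPALISWIKRKRQQ",
    buforin = "TRSSRAGLQFPVGRVHRLLRK",
    MM1 = "GIGAVLKALTTGLGALASAIKRKRQQ",
    AR23 = "AIGSILGALAKGLPTLISWIKNR",
    RV23 = "RIGVLLARLPKLFSLFKLMGKKV")
}

#' Peptide feature report
#'
#' One row per record: name, length, cationic and anionic counts,
#' hydrophobic fraction, face angle, and (when a geometry is given) the
#' axial cationic density per window. The hydrophobic set used is recorded
#' in the `hydrophobicSet` attribute of the result.
#'
#' @param records list of [PeptideRecord-class] objects.
#' @param geometry optional [protofibrilGeometry()] result applied to all
#'   records.
#' @param window axial window in nm for the density column.
#' @return data.frame.
#' @export
peptideReport <- function(records, geometry = NULL, window = 3.4) {
  rows <- lapply(records, function(r) {
    data.frame(
      name = r@name, length = nchar(r@sequence),
      cationic = countResidues(r, "cationic"),
      anionic = countResidues(r, "anionic"),
      hydrophobicFraction = hydrophobicFraction(r),
      faceAngle = hydrophobicFaceAngle(r),
      axialDensity = if (is.null(geometry)) NA_real_ else
        axialChargeDensity(r, geometry, window)$density,
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "hydrophobicSet") <-
    paste(records[[1]]@hydrophobicSet, collapse = "")
  out
}
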