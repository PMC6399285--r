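# Measured Bragg peak tables shipped as plain-text fixtures under
# inst/extdata: hand-indexed reflection lists (q, h, k, l) for the
# peptide-DNA complexes, usable in peak-list mode when no raw spectrum is
# available.

#' Read a peak-list table
#'
#' A peak list is delimited text with a header row and columns q (inverse
#' Angstrom) plus Miller indices h, k and optionally l; '#' lines are
#' comments. Peak lists drive the label-driven ("peak-list") analysis mode,
#' which bypasses automatic reflection assignment.
#'
#' @param path file path.
#' @return data.frame with columns qMeasured, h, k, l, label, matched.
#' @seealso [measuredPeakList()]
#' @export
readPeakList <- function(path) {
  if (!file.exists(path)) stop("peak list not found: ", path)
  df <- utils::read.table(path, header = TRUE, comment.char = "#")
  if (!all(c("q", "h", "k") %in% names(df)))
    stop("peak list needs columns q, h, k (and optionally l): ", path)
  if (!"l" %in% names(df)) df$l <- 0L
  data.frame(qMeasured = df$q, h = df$h, k = df$k, l = df$l,
             label = sprintf("%d%d%d", df$h, df$k, df$l),
             qPredicted = NA_real_, residual = NA_real_, matched = TRUE,
             stringsAsFactors = FALSE)
}

#' Bundled measured peak lists
#'
#' Returns one of the hand-indexed reflection tables shipped with the
#' package: the twelve tetragonal reflections of the melittin-dsDNA
#' complex or the five square-lattice reflections of the LL37-dsDNA
#' complex.
#'
#' @param sample `"melittin_dna"` or `"ll37_dna"`.
#' @return data.frame as from [readPeakList()].
#' @examples
#' fitTetragonalLattice(measuredPeakList("melittin_dna"))
#' @export
measuredPeakList <- function(sample = c("melittin_dna", "ll37_dna")) {
  sample <- match.arg(sample)
  path <- system.file("extdata", paste0(sample, "_peaks.tsv"),
                      package = "mesoSAXS", mustWork = TRUE)
  readPeakList(path)
}
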