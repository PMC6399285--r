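# Permitted reflections per mesophase. Peak positions follow
#   lamellar:            q_n  = (2*pi/d) * n
#   square columnar:     q_hk = (2*pi/d) * sqrt(h^2 + k^2)
#   hexagonal columnar:  q_hk = (2*pi/d) * sqrt(h^2 + h*k + k^2) (normalized
#                        so the first reflection modulus is 1 is NOT applied;
#                        moduli are the raw index expressions)
#   tetragonal columnar: q_hkl = 2*pi*sqrt((h^2+k^2)/d^2 + l^2/c^2)
#   Pn3m cubic:          q_hkl = (2*pi/a) * sqrt(h^2+k^2+l^2), with the
#                        space-group reflection conditions below.
#
# Pn3m reflection conditions (space group 224): a reflection with one zero
# index (0kl and cubic permutations) requires the sum of the two nonzero
# indices to be even (which subsumes h00: h even); reflections with no zero
# index are unconditionally allowed. This reproduces the characteristic
# ratio sequence sqrt(2):sqrt(3):sqrt(4):sqrt(6):sqrt(8):sqrt(9) and
# continues it (sqrt(10), sqrt(11), sqrt(12), sqrt(14), ...).

.pn3mAllowed <- function(h, k, l) {
  idx <- c(h, k, l)
  if (all(idx == 0)) return(FALSE)
  if (any(idx == 0)) {
    nz <- idx[idx != 0]
    # one or two zeros: the remaining index sum must be even
    return(sum(nz) %% 2 == 0)
  }
  TRUE
}

#' Enumerate permitted reflections for a mesophase
#'
#' Builds the ordered reflection catalog for one of the supported
#' mesophases, up to a maximum Miller index. For the one-parameter phases
#' the catalog is the deduplicated, strictly increasing list of
#' dimensionless moduli (the factor multiplying 2*pi/d in the peak
#' position). The tetragonal columnar phase needs two lattice parameters,
#' so its entries are the index combinations (h^2+k^2, l) and the modulus
#' column is NA.
#'
#' @param phase one of `"lamellar"`, `"square_columnar"`,
#'   `"hexagonal_columnar"`, `"tetragonal_columnar"`, `"cubic_pn3m"`.
#' @param maxIndex modulus cutoff (>= 1): reflections are kept while their
#'   dimensionless modulus does not exceed `maxIndex`. A modulus cutoff
#'   (rather than a bound on individual indices) makes catalogs
#'   prefix-stable: raising it only appends entries. For the tetragonal
#'   phase it bounds sqrt(h^2+k^2) and l separately.
#' @return a [PhaseCatalog-class] object.
#' @examples
#' reflections(permittedModuli("square_columnar", 3))
#' # Pn3m starts at sqrt(2), sqrt(3), sqrt(4), sqrt(6), sqrt(8), sqrt(9)
#' reflections(permittedModuli("cubic_pn3m", 3))$modulus[1:6]^2
#' @export
permittedModuli <- function(phase, maxIndex = 3L) {
  if (!is.character(phase) || !phase %in% .PHASES)
    stop("unknown phase '", phase, "'; supported phases: ",
         paste(.PHASES, collapse = ", "))
  maxIndex <- as.integer(maxIndex)
  if (maxIndex < 1L) stop("maxIndex must be >= 1")
  refl <- switch(phase,
    lamellar = {
      n <- seq_len(maxIndex)
      data.frame(label = sprintf("%d", n), h = n, k = 0L, l = 0L,
                 modulus = as.numeric(n))
    },
    square_columnar = {
      g <- expand.grid(h = 0:maxIndex, k = 0:maxIndex)
      g <- g[g$h >= g$k & (g$h + g$k) > 0, ]
      g$modulus <- sqrt(g$h^2 + g$k^2)
      g <- g[g$modulus <= maxIndex + 1e-9, ]
      g <- g[order(g$modulus, g$h), ]
      g <- g[!duplicated(signif(g$modulus, 12)), ]
      data.frame(label = sprintf("%d%d", g$h, g$k), h = g$h, k = g$k,
                 l = 0L, modulus = g$modulus)
    },
    hexagonal_columnar = {
      g <- expand.grid(h = 0:maxIndex, k = 0:maxIndex)
      g <- g[g$h >= g$k & (g$h + g$k) > 0, ]
      g$modulus <- sqrt(g$h^2 + g$h * g$k + g$k^2)
      g <- g[g$modulus <= maxIndex + 1e-9, ]
      g <- g[order(g$modulus, g$h), ]
      g <- g[!duplicated(signif(g$modulus, 12)), ]
      data.frame(label = sprintf("%d%d", g$h, g$k), h = g$h, k = g$k,
                 l = 0L, modulus = g$modulus)
    },
    cubic_pn3m = {
      g <- expand.grid(h = 0:maxIndex, k = 0:maxIndex, l = 0:maxIndex)
      g <- g[g$h >= g$k & g$k >= g$l & (g$h + g$k + g$l) > 0, ]
      ok <- mapply(.pn3mAllowed, g$h, g$k, g$l)
      g <- g[ok, ]
      g$modulus <- sqrt(g$h^2 + g$k^2 + g$l^2)
      g <- g[g$modulus <= maxIndex + 1e-9, ]
      g <- g[order(g$modulus, g$h, g$k), ]
      g <- g[!duplicated(signif(g$modulus, 12)), ]
      data.frame(label = sprintf("%d%d%d", g$h, g$k, g$l), h = g$h,
                 k = g$k, l = g$l, modulus = g$modulus)
    },
    tetragonal_columnar = {
      g <- expand.grid(h = 0:maxIndex, k = 0:maxIndex, l = 0:maxIndex)
      g <- g[g$h >= g$k & (g$h + g$k + g$l) > 0, ]
      # two lattice parameters: order by the in-plane index, then l;
      # dedupe on the (h^2+k^2, l) pair that determines the position
      g$N <- g$h^2 + g$k^2
      g <- g[g$N <= maxIndex^2 + 1e-9, ]
      g <- g[order(g$N, g$l, g$h), ]
      g <- g[!duplicated(g[, c("N", "l")]), ]
      data.frame(label = sprintf("%d%d%d", g$h, g$k, g$l), h = g$h,
                 k = g$k, l = g$l, modulus = NA_real_)
    })
  rownames(refl) <- NULL
  new("PhaseCatalog", phase = phase, reflections = refl,
      nParams = if (phase == "tetragonal_columnar") 2L else 1L)
}

#' Write a catalog as delimited text
#'
#' @param catalog a [PhaseCatalog-class] object.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeCatalog <- function(catalog, path) {
  stopifnot(is(catalog, "PhaseCatalog"))
  df <- cbind(phase = catalog@phase, catalog@reflections)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
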