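# Negative Gaussian curvature (NGC) induced in membranes, quantified from
# the lattice parameter of a bicontinuous cubic phase. Per unit cell the
# average Gaussian curvature of the minimal midplane surface is
#   <K> = 2*pi*chi / (A0 * a^2),
# with chi the Euler characteristic of the surface per unit cell and A0 its
# dimensionless area. For the Pn3m (double-diamond) aspect chi = -2 and
# A0 = 1.919, so <K> is negative: the surface is saddle-shaped everywhere.

#' Topological constants of a cubic aspect
#'
#' Ships Pn3m constants (chi = -2, A0 = 1.919). Slots for the Im3m and
#' Ia3d aspects exist but have no default values here; users must supply
#' literature values for them explicitly.
#'
#' @param phase `"pn3m"`, `"im3m"` or `"ia3d"`.
#' @param chi,A0 Euler characteristic and dimensionless unit-cell surface
#'   area; required for aspects other than Pn3m.
#' @return list with elements phase, chi, A0.
#' @export
cubicPhaseConstants <- function(phase = c("pn3m", "im3m", "ia3d"),
                                chi = NULL, A0 = NULL) {
  phase <- match.arg(phase)
  if (phase == "pn3m") {
    chi <- chi %||% -2
    A0 <- A0 %||% 1.919
  } else if (is.null(chi) || is.null(A0)) {
    stop("no built-in constants for ", phase,
         "; supply chi and A0 (literature values) explicitly")
  }
  if (!isTRUE(A0 > 0)) stop("A0 must be > 0")
  list(phase = phase, chi = chi, A0 = A0)
}

#' Average Gaussian curvature per cubic unit cell
#'
#' <K> = 2*pi*chi/(A0*a^2); negative for the saddle-forming bicontinuous
#' aspects (chi < 0).
#'
#' @param a cubic lattice parameter in nm, > 0.
#' @param constants from [cubicPhaseConstants()].
#' @return list with `K` (nm^-2, signed) and `Kmagnitude`.
#' @examples
#' ngcPerUnitCell(15.4)$K # -2.76e-2 nm^-2
#' @export
ngcPerUnitCell <- function(a, constants = cubicPhaseConstants("pn3m")) {
  if (!isTRUE(a > 0)) stop("lattice parameter a must be > 0")
  K <- 2 * pi * constants$chi / (constants$A0 * a^2)
  list(K = K, Kmagnitude = abs(K))
}

#' Cubic lattice parameter from a curvature magnitude
#'
#' Algebraic inverse of [ngcPerUnitCell()]:
#' a = sqrt(2*pi*|chi|/(A0*|K|)).
#'
#' @param Kmagnitude |<K>| in nm^-2, > 0.
#' @param constants from [cubicPhaseConstants()].
#' @return lattice parameter a in nm.
#' @examples
#' latticeFromNGC(2.75e-2) # 15.4 nm
#' @export
latticeFromNGC <- function(Kmagnitude,
                           constants = cubicPhaseConstants("pn3m")) {
  if (!isTRUE(Kmagnitude > 0)) stop("Kmagnitude must be > 0")
  sqrt(2 * pi * abs(constants$chi) / (constants$A0 * Kmagnitude))
}

#' One-line curvature report
#'
#' @param a cubic lattice parameter (nm).
#' @param constants from [cubicPhaseConstants()].
#' @return data.frame with columns phase, a_nm, chi, A0, K_nm2.
#' @export
curvatureReport <- function(a, constants = cubicPhaseConstants("pn3m")) {
  k <- ngcPerUnitCell(a, constants)
  data.frame(phase = constants$phase, a_nm = a, chi = constants$chi,
             A0 = constants$A0, K_nm2 = k$K)
}
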