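# Lattice indexing: assign measured Bragg peaks to catalog reflections and
# regress lattice parameters.
#
# All regressions are through-origin least squares on q^2, which is exactly
# linear in the unknowns u = (2*pi/d)^2 (and v = (2*pi/c)^2 for the
# tetragonal phase): the defining lattice equations have no offset. R^2 is
# therefore computed with the UNCENTERED total sum of squares in q^2 space
# and is not comparable to a centered R^2.

.A_PER_NM <- 10  # q handled in A^-1, spacings reported in nm

.newAssignment <- function(qMeasured) {
  data.frame(qMeasured = qMeasured, label = NA_character_,
             h = NA_integer_, k = NA_integer_, l = NA_integer_,
             qPredicted = NA_real_, residual = NA_real_, matched = FALSE,
             stringsAsFactors = FALSE)
}

#' Assign measured peaks to catalog reflections by ratio matching
#'
#' Normalizes every measured position by the first peak and greedily
#' matches each ratio to the nearest unused catalog modulus ratio within a
#' relative tolerance. Catalog entries may be skipped (missing reflections
#' are allowed and carry no penalty); measured peaks with no catalog match
#' within tolerance are returned flagged as unmatched.
#'
#' The tolerance applies to the ratio q_i/q_1, so a first peak that itself
#' deviates from the best-fit lattice inflates the apparent mismatch of the
#' higher orders; reproducing hand-indexed assignments of real data can
#' require a looser tolerance than the default.
#'
#' @param peaks numeric vector of measured peak positions (inverse
#'   Angstrom), increasing.
#' @param catalog a one-parameter [PhaseCatalog-class] (the tetragonal
#'   catalog cannot be reduced to a modulus list; use [selectPhase()]).
#' @param relTolerance relative matching tolerance in (0, 0.1].
#' @return data.frame with columns qMeasured, label, h, k, l, qPredicted,
#'   residual, matched (qPredicted/residual filled by the fit functions).
#' @export
assignReflections <- function(peaks, catalog, relTolerance = 0.015) {
  stopifnot(is(catalog, "PhaseCatalog"))
  if (!length(peaks)) stop("at least one measured peak is required")
  if (!(relTolerance > 0 && relTolerance <= 0.1))
    stop("relTolerance must lie in (0, 0.1]")
  if (catalog@phase == "tetragonal_columnar")
    stop("tetragonal positions depend on two parameters; ",
         "use selectPhase() or fitTetragonalLattice() with explicit labels")
  peaks <- sort(peaks)
  out <- .newAssignment(peaks)
  refl <- catalog@reflections
  ratios <- peaks / peaks[1]
  cr <- refl$modulus / refl$modulus[1]
  used <- rep(FALSE, length(cr))
  for (i in seq_along(ratios)) {
    rel <- abs(ratios[i] - cr) / cr
    rel[used] <- Inf
    j <- which.min(rel)
    if (is.finite(rel[j]) && rel[j] <= relTolerance) {
      used[j] <- TRUE
      out$label[i] <- refl$label[j]
      out$h[i] <- refl$h[j]; out$k[i] <- refl$k[j]; out$l[i] <- refl$l[j]
      out$matched[i] <- TRUE
    }
  }
  out
}

.modulus2 <- function(phase, h, k, l) {
  switch(phase,
    lamellar = h^2,
    square_columnar = h^2 + k^2,
    hexagonal_columnar = h^2 + h * k + k^2,
    cubic_pn3m = h^2 + k^2 + l^2,
    stop("no single modulus for phase ", phase))
}

# Through-origin LS of q^2 on the squared modulus for one-parameter phases.
.fitOneParam <- function(phase, assignments) {
  m <- assignments[assignments$matched, , drop = FALSE]
  if (!nrow(m)) stop("no matched assignments to fit")
  N <- .modulus2(phase, m$h, m$k, m$l)
  if (all(N == 0)) stop("all squared moduli are zero; nothing to fit")
  q2 <- m$qMeasured^2
  slope <- sum(N * q2) / sum(N^2)
  spacingA <- 2 * pi / sqrt(slope)
  qpred <- sqrt(slope * N)
  r2 <- 1 - sum((q2 - slope * N)^2) / sum(q2^2)
  asn <- assignments
  idx <- which(asn$matched)
  asn$qPredicted[idx] <- qpred
  asn$residual[idx] <- asn$qMeasured[idx] - qpred
  spacing_nm <- spacingA / .A_PER_NM
  if (phase == "cubic_pn3m")
    new("LatticeFit", phase = phase, a = spacing_nm, rSquared = r2,
        assignments = asn, nMatched = as.integer(nrow(m)))
  else
    new("LatticeFit", phase = phase, d = spacing_nm, rSquared = r2,
        assignments = asn, nMatched = as.integer(nrow(m)))
}

.asAssignment <- function(assignments) {
  if (!is.data.frame(assignments))
    stop("assignments must be a data.frame")
  df <- assignments
  if (!"l" %in% names(df)) df$l <- 0L
  if (!"k" %in% names(df)) df$k <- 0L
  if (!"label" %in% names(df))
    df$label <- sprintf("%d%d%d", df$h, df$k, df$l)
  if (!"matched" %in% names(df)) df$matched <- TRUE
  if (!"qPredicted" %in% names(df)) df$qPredicted <- NA_real_
  if (!"residual" %in% names(df)) df$residual <- NA_real_
  df
}

#' Fit a 2D square columnar lattice
#'
#' Through-origin least squares of q^2 on h^2 + k^2; the slope s gives the
#' inter-column spacing d = 2*pi/sqrt(s), reported in nm.
#'
#' @param assignments data.frame with columns qMeasured, h, k (and
#'   optionally label/matched), e.g. from [assignReflections()].
#' @return a [LatticeFit-class] object with d (nm), uncentered R^2 in q^2
#'   space, and per-peak predictions and residuals.
#' @examples
#' pk <- data.frame(qMeasured = (2 * pi / 34) * sqrt(c(1, 2, 4, 5, 8)),
#'                  h = c(1, 1, 2, 2, 2), k = c(0, 1, 0, 1, 2))
#' latticeD(fitSquareLattice(pk)) # 3.4 nm
#' @export
fitSquareLattice <- function(assignments) {
  .fitOneParam("square_columnar", .asAssignment(assignments))
}

#' Fit a Pn3m cubic lattice
#'
#' Through-origin least squares of q^2 on h^2 + k^2 + l^2; reports the
#' cubic lattice parameter a = 2*pi/sqrt(slope) in nm.
#'
#' @param assignments data.frame with columns qMeasured, h, k, l.
#' @return a [LatticeFit-class] object with a (nm).
#' @export
fitCubicLattice <- function(assignments) {
  .fitOneParam("cubic_pn3m", .asAssignment(assignments))
}

#' Fit a 3D tetragonal columnar lattice
#'
#' Two-parameter through-origin least squares of q^2 on (h^2 + k^2) and
#' l^2, per q_hkl = 2*pi*sqrt((h^2+k^2)/d^2 + l^2/c^2): the coefficients
#' u and v give d = 2*pi/sqrt(u) and c = 2*pi/sqrt(v), both reported in nm.
#' Requires at least one reflection with h^2+k^2 > 0 and one with l > 0;
#' otherwise the corresponding parameter is indeterminate and an error
#' names the missing reflection class. Per-peak residuals are reported so
#' outlying input positions stay visible rather than being absorbed
#' silently.
#'
#' @param assignments data.frame with columns qMeasured, h, k, l.
#' @return a [LatticeFit-class] object with d and c (nm).
#' @export
fitTetragonalLattice <- function(assignments) {
  asn <- .asAssignment(assignments)
  m <- asn[asn$matched, , drop = FALSE]
  if (nrow(m) < 2L)
    stop("tetragonal fit needs at least 2 assigned peaks")
  N <- m$h^2 + m$k^2
  l2 <- m$l^2
  if (all(N == 0))
    stop("no in-plane (h k 0 / h k l, h^2+k^2 > 0) reflection: ",
         "d is indeterminate")
  if (all(l2 == 0))
    stop("no out-of-plane (l > 0) reflection: c is indeterminate")
  q2 <- m$qMeasured^2
  fit <- stats::lm(q2 ~ 0 + N + l2)
  if (fit$rank < 2L) stop("tetragonal design matrix is rank-deficient")
  u <- unname(stats::coef(fit)["N"]); v <- unname(stats::coef(fit)["l2"])
  if (!isTRUE(u > 0) || !isTRUE(v > 0))
    stop("tetragonal fit produced a non-positive squared slope")
  qpred <- sqrt(u * N + v * l2)
  r2 <- 1 - sum((q2 - (u * N + v * l2))^2) / sum(q2^2)
  idx <- which(asn$matched)
  asn$qPredicted[idx] <- qpred
  asn$residual[idx] <- asn$qMeasured[idx] - qpred
  new("LatticeFit", phase = "tetragonal_columnar",
      d = 2 * pi / sqrt(u) / .A_PER_NM, c = 2 * pi / sqrt(v) / .A_PER_NM,
      rSquared = r2, assignments = asn, nMatched = as.integer(nrow(m)))
}

#' First-peak spacing estimate for disordered bundles
#'
#' For a columnar bundle with only short-ranged order the inter-column
#' spacing is estimated from the single diffraction feature as
#' d = 2*pi/q1.
#'
#' @param q1 first peak position (inverse Angstrom), > 0.
#' @return spacing in nm.
#' @examples
#' estimateDisorderedSpacing(0.170) # 3.70 nm
#' @export
estimateDisorderedSpacing <- function(q1) {
  if (!isTRUE(q1 > 0)) stop("q1 must be > 0")
  2 * pi / q1 / .A_PER_NM
}

# Auto-indexing of the tetragonal phase: seed the in-plane parameter from
# the l = 0 (square sub-catalog) series, scan c hypotheses from peaks that
# the square layer leaves unassigned, then jointly refine.
.autoTetragonal <- function(peaks, relTolerance, maxIndex = 3L) {
  peaks <- sort(peaks)
  sq <- assignReflections(peaks, permittedModuli("square_columnar",
                                                 maxIndex), relTolerance)
  if (sum(sq$matched) < 2L) return(NULL)
  d0A <- 2 * pi / sqrt(sum((sq$h[sq$matched]^2 + sq$k[sq$matched]^2) *
                             sq$qMeasured[sq$matched]^2) /
                       sum((sq$h[sq$matched]^2 + sq$k[sq$matched]^2)^2))
  unassigned <- peaks[!sq$matched]
  if (!length(unassigned)) return(NULL)  # pure square: no l > 0 evidence
  sqcat <- permittedModuli("square_columnar", maxIndex)@reflections
  combos <- expand.grid(i = c(0L, seq_len(nrow(sqcat))), l = 0:maxIndex)
  combos <- combos[!(combos$i == 0L & combos$l == 0L), ]
  combos$h <- ifelse(combos$i == 0L, 0L, sqcat$h[pmax(combos$i, 1L)])
  combos$k <- ifelse(combos$i == 0L, 0L, sqcat$k[pmax(combos$i, 1L)])
  combos$N <- combos$h^2 + combos$k^2
  u0 <- (2 * pi / d0A)^2
  best <- NULL
  for (qu in unassigned) {
    for (lhyp in 1:2) {
      v0 <- (qu^2) / lhyp^2
      cand <- .matchTetragonal(peaks, combos, u0, v0, relTolerance)
      score <- c(sum(cand$matched), -sum((cand$residual / cand$qMeasured)^2,
                                         na.rm = TRUE))
      if (is.null(best) || score[1] > best$score[1] ||
          (score[1] == best$score[1] && score[2] > best$score[2]))
        best <- list(asn = cand, score = score)
    }
  }
  if (is.null(best) || sum(best$asn$matched) < 2L) return(NULL)
  ok <- best$asn$matched & (best$asn$h^2 + best$asn$k^2 + best$asn$l^2) > 0
  if (!any(best$asn$l[best$asn$matched] > 0)) return(NULL)
  fit <- tryCatch(fitTetragonalLattice(best$asn), error = function(e) NULL)
  if (is.null(fit)) return(NULL)
  # one re-match pass with the refined parameters
  uA <- (2 * pi / (fit@d * .A_PER_NM))^2
  vA <- (2 * pi / (fit@c * .A_PER_NM))^2
  asn2 <- .matchTetragonal(peaks, combos, uA, vA, relTolerance)
  if (sum(asn2$matched) >= sum(best$asn$matched))
    fit <- tryCatch(fitTetragonalLattice(asn2), error = function(e) fit)
  fit
}

.matchTetragonal <- function(peaks, combos, u, v, relTolerance) {
  out <- .newAssignment(peaks)
  qpred <- sqrt(u * combos$N + v * combos$l^2)
  used <- rep(FALSE, nrow(combos))
  for (i in seq_along(peaks)) {
    rel <- abs(peaks[i] - qpred) / qpred
    rel[used] <- Inf
    j <- which.min(rel)
    if (is.finite(rel[j]) && rel[j] <= relTolerance) {
      used[j] <- TRUE
      out$h[i] <- combos$h[j]; out$k[i] <- combos$k[j]
      out$l[i] <- combos$l[j]
      out$label[i] <- sprintf("%d%d%d", combos$h[j], combos$k[j],
                              combos$l[j])
      out$matched[i] <- TRUE
    }
  }
  out
}

# Fraction of catalog reflections up to the highest matched order that are
# actually observed. Separates nested catalogs (a lamellar series indexes
# on the square and hexagonal catalogs too, with exactly the same R^2).
.catalogCoverage <- function(fit, maxIndex = 3L) {
  asn <- fit@assignments
  m <- asn[asn$matched, , drop = FALSE]
  if (!nrow(m)) return(0)
  qmax <- max(m$qMeasured) * 1.001
  if (fit@phase == "tetragonal_columnar") {
    cat <- permittedModuli("tetragonal_columnar", maxIndex)@reflections
    u <- (2 * pi / (fit@d * .A_PER_NM))^2
    v <- (2 * pi / (fit@c * .A_PER_NM))^2
    qpred <- sqrt(u * (cat$h^2 + cat$k^2) + v * cat$l^2)
  } else {
    cat <- permittedModuli(fit@phase, maxIndex)@reflections
    par <- if (fit@phase == "cubic_pn3m") fit@a else fit@d
    qpred <- 2 * pi / (par * .A_PER_NM) * cat$modulus
  }
  nrow(m) / max(1L, sum(qpred <= qmax))
}

#' Classify a peak list among candidate mesophases
#'
#' Runs reflection assignment and lattice regression for every candidate
#' phase. A candidate is viable when at least `minMatched` peaks are
#' assigned and every matched residual is within the relative tolerance.
#' Viable candidates are ranked by number of matched peaks, then by catalog
#' coverage (the fraction of permitted reflections up to the highest
#' matched order that are observed -- this separates a lamellar series,
#' which also indexes perfectly on the square and hexagonal catalogs, from
#' the denser catalogs it under-fills), then by R^2. When no candidate is
#' viable the verdict is "disordered" with the first-peak spacing estimate
#' d = 2*pi/q1.
#'
#' @param peaks numeric vector of measured peak positions (inverse
#'   Angstrom).
#' @param candidates character vector of phase names to try.
#' @param minMatched minimum assigned peaks to call a lattice (default 3,
#'   below which a single broad feature is treated as disordered).
#' @param relTolerance relative tolerance for ratio matching and residuals.
#' @param maxIndex catalog depth.
#' @return a [LatticeFit-class] object; `phaseName(fit) == "disordered"`
#'   signals the fallback verdict.
#' @export
selectPhase <- function(peaks, candidates = .PHASES, minMatched = 3L,
                        relTolerance = 0.015, maxIndex = 4L) {
  if (!length(peaks)) stop("no peaks supplied")
  if (!length(candidates)) stop("no candidate phases supplied")
  bad <- setdiff(candidates, .PHASES)
  if (length(bad))
    stop("unknown phase(s): ", paste(bad, collapse = ", "),
         "; supported: ", paste(.PHASES, collapse = ", "))
  peaks <- sort(peaks)
  fits <- list()
  for (ph in candidates) {
    fit <- if (ph == "tetragonal_columnar") {
      .autoTetragonal(peaks, relTolerance, maxIndex)
    } else {
      asn <- assignReflections(peaks, permittedModuli(ph, maxIndex),
                               relTolerance)
      if (sum(asn$matched) >= 1L)
        tryCatch(.fitOneParam(ph, asn), error = function(e) NULL)
      else NULL
    }
    if (is.null(fit)) next
    m <- fit@assignments[fit@assignments$matched, , drop = FALSE]
    viable <- fit@nMatched >= minMatched &&
      all(abs(m$residual) / m$qMeasured <= relTolerance)
    if (viable)
      fits[[ph]] <- list(fit = fit,
                         coverage = .catalogCoverage(fit, maxIndex))
  }
  if (!length(fits)) {
    asn <- .newAssignment(peaks)
    asn$label[1] <- "q1"; asn$matched[1] <- TRUE
    return(new("LatticeFit", phase = "disordered",
               d = estimateDisorderedSpacing(peaks[1]),
               assignments = asn, nMatched = 1L))
  }
  key <- vapply(fits, function(f)
    c(f$fit@nMatched, f$coverage, f$fit@rSquared), numeric(3))
  ord <- order(key[1, ], key[2, ], key[3, ], decreasing = TRUE)
  fits[[ord[1]]]$fit
}
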