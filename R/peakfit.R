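# Bragg peak line shapes and nonlinear fitting.
#
# The structure factor of a finite nanocrystalline domain is modeled as an
# area-normalized squared-Lorentzian,
#   S(q) = h^3 / (4*pi*(|q - q1|^2 + (h/2)^2)^2),
# whose width parameter h feeds the Warren domain-size estimate; disordered
# bundles with exponentially decaying positional correlations give a plain
# Lorentzian, S(q) = (1/pi)*(h/2)/((q - q1)^2 + (h/2)^2). Fits multiply the
# normalized shape by a free amplitude so h keeps its physical meaning.

.peakShape <- function(kind, q, q1, h) {
  if (h <= 0) stop("width parameter h must be > 0")
  switch(kind,
    squared_lorentzian = h^3 / (4 * pi * ((q - q1)^2 + (h / 2)^2)^2),
    lorentzian = (1 / pi) * (h / 2) / ((q - q1)^2 + (h / 2)^2),
    stop("unknown peak kind: ", kind))
}

#' Evaluate a peak model on a q grid
#'
#' Returns amplitude times the area-normalized line shape. At the center the
#' normalized squared-Lorentzian equals 4/(pi*h) and the normalized
#' Lorentzian 2/(pi*h).
#'
#' @param model a [PeakModel-class] object.
#' @param q numeric momentum-transfer values (inverse Angstrom).
#' @return numeric intensities.
#' @export
evaluatePeak <- function(model, q) {
  stopifnot(is(model, "PeakModel"))
  model@amplitude * .peakShape(model@kind, q, model@q1, model@h)
}

#' Fit a single Bragg peak by nonlinear least squares
#'
#' Fits amplitude, center q1 and width h of the chosen line-shape family
#' over a q window via Levenberg-Marquardt least squares
#' ([minpack.lm::nlsLM()]). The initial center defaults to the argmax inside
#' the window and the initial width to half the window width. On
#' non-convergence the last iterate is returned with the `converged` flag
#' cleared and a warning.
#'
#' @param profile a [Profile1D-class] object (background-subtracted).
#' @param window length-2 numeric, q interval to fit over; must contain at
#'   least 5 points.
#' @param kind `"squared_lorentzian"` (default, ordered nanocrystals) or
#'   `"lorentzian"` (disordered bundles).
#' @param initial optional named list with any of `q1`, `h`, `amplitude`.
#' @return a [PeakModel-class] object with fit standard errors.
#' @examples
#' q <- seq(0.10, 0.24, by = 2e-4)
#' truth <- PeakModel("squared_lorentzian", q1 = 0.170, h = 0.02)
#' p <- Profile1D(q, evaluatePeak(truth, q))
#' fitPeak(p, c(0.12, 0.22))
#' @export
fitPeak <- function(profile, window,
                    kind = c("squared_lorentzian", "lorentzian"),
                    initial = list()) {
  stopifnot(is(profile, "Profile1D"))
  kind <- match.arg(kind)
  if (length(window) != 2L) stop("window must be a length-2 q interval")
  sel <- profile@q >= min(window) & profile@q <= max(window)
  if (sum(sel) < 5L)
    stop("fit window must contain at least 5 points (has ",
         sum(sel), ")")
  q <- profile@q[sel]; y <- profile@intensity[sel]
  imax <- which.max(y)
  if (imax %in% c(1L, length(y)))
    warning("fit window has no interior maximum; best-effort fit")
  q1_0 <- initial$q1 %||% q[imax]
  h_0 <- initial$h %||% (diff(range(q)) / 2)
  amp_0 <- initial$amplitude %||%
    max(max(y) / .peakShape(kind, q1_0, q1_0, h_0), .Machine$double.eps)
  fit <- tryCatch(
    minpack.lm::nlsLM(
      y ~ A * .peakShape(kind, q, q1, h),
      start = list(A = amp_0, q1 = q1_0, h = h_0),
      lower = c(A = .Machine$double.eps, q1 = min(q), h = 1e-8),
      upper = c(A = Inf, q1 = max(q), h = diff(range(q)) * 10),
      control = minpack.lm::nls.lm.control(maxiter = 200, ftol = 1e-14,
                                           ptol = 1e-14)),
    error = function(e) e)
  if (inherits(fit, "error"))
    stop("peak fit failed in window [", min(window), ", ", max(window),
         "]: ", conditionMessage(fit))
  cf <- stats::coef(fit)
  se <- tryCatch(sqrt(diag(stats::vcov(fit))),
                 error = function(e) rep(NA_real_, 3))
  conv <- isTRUE(fit$convInfo$isConv) || is.null(fit$convInfo)
  if (!conv)
    warning("peak fit did not converge; reporting last iterate")
  PeakModel(kind = kind, q1 = unname(cf["q1"]), h = unname(cf["h"]),
            amplitude = unname(cf["A"]),
            centerUncertainty = unname(se[2]),
            widthUncertainty = unname(se[3]), converged = conv)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Detect candidate Bragg peaks
#'
#' Smooths the profile with a centered moving average, finds strict local
#' maxima, and keeps those whose prominence (height above the higher of the
#' two flanking valleys, valleys delimited by the nearest higher point or
#' the profile edge) exceeds `minProminence` times the maximum smoothed
#' intensity. Intended for background-subtracted profiles.
#'
#' @param profile a [Profile1D-class] object.
#' @param minProminence prominence threshold as a fraction of the maximum
#'   smoothed intensity.
#' @param smoothingHalfwidth half-width of the moving average, in points
#'   (0 disables smoothing).
#' @return numeric vector of candidate peak centers (q, increasing);
#'   possibly empty.
#' @export
detectPeaks <- function(profile, minProminence = 0.05,
                        smoothingHalfwidth = 2L) {
  stopifnot(is(profile, "Profile1D"))
  y <- profile@intensity
  k <- as.integer(smoothingHalfwidth)
  if (k > 0L) {
    w <- 2L * k + 1L
    ys <- as.numeric(stats::filter(y, rep(1 / w, w), sides = 2))
    # moving average is undefined at the edges; fall back to the raw signal
    ys[is.na(ys)] <- y[is.na(ys)]
  } else ys <- y
  n <- length(ys)
  if (n < 3L) return(numeric(0))
  cand <- which(ys[2:(n - 1)] > ys[1:(n - 2)] &
                ys[2:(n - 1)] > ys[3:n]) + 1L
  if (!length(cand)) return(numeric(0))
  prom <- vapply(cand, function(i) {
    higherL <- which(ys[seq_len(i - 1L)] > ys[i])
    lo <- if (length(higherL)) max(higherL) else 1L
    higherR <- which(ys[(i + 1L):n] > ys[i]) + i
    hi <- if (length(higherR)) min(higherR) else n
    base <- max(min(ys[lo:i]), min(ys[i:hi]))
    ys[i] - base
  }, numeric(1))
  keep <- prom > minProminence * max(ys)
  sort(profile@q[cand[keep]])
}

#' Fit several peaks with iterated tail subtraction
#'
#' Each peak is fitted independently in its own window, but because
#' Lorentzian-family tails extend into neighboring windows, the fits are
#' iterated: on every pass each peak is refitted on the profile minus the
#' current model of all other peaks. On noiseless data this converges to
#' the exact generating parameters.
#'
#' @param profile a background-subtracted [Profile1D-class] object.
#' @param centers numeric vector of approximate peak centers.
#' @param kind line-shape family for every peak.
#' @param windowHalfwidth half-width of each fit window (inverse Angstrom);
#'   default 1.5 times the estimated full width at half maximum.
#' @param iterations number of tail-subtraction passes.
#' @return list of [PeakModel-class] objects, ordered by center.
#' @seealso [fitPeak()]
#' @export
fitPeaks <- function(profile, centers,
                     kind = c("squared_lorentzian", "lorentzian"),
                     windowHalfwidth = NULL, iterations = 4L) {
  stopifnot(is(profile, "Profile1D"))
  kind <- match.arg(kind)
  centers <- sort(centers)
  if (!length(centers)) return(list())
  q <- profile@q
  halfwidths <- vapply(centers, function(ctr) {
    if (!is.null(windowHalfwidth)) return(windowHalfwidth)
    # grid estimate of the half-width at half maximum around this center
    i0 <- which.min(abs(q - ctr))
    ymax <- profile@intensity[i0]
    above <- profile@intensity >= ymax / 2
    left <- i0; while (left > 1L && above[left - 1L]) left <- left - 1L
    right <- i0; while (right < length(q) && above[right + 1L])
      right <- right + 1L
    max(3 * (q[right] - q[left]), 6 * min(diff(q)))
  }, numeric(1))
  # clip each window at the midpoint to the neighboring detected peak so a
  # fit can never wander onto a neighbor's core; residual tails are handled
  # by the subtraction passes
  step <- min(diff(q))
  lo <- pmax(centers - halfwidths,
             c(-Inf, (centers[-length(centers)] + centers[-1]) / 2))
  hi <- pmin(centers + halfwidths,
             c((centers[-length(centers)] + centers[-1]) / 2, Inf))
  tooNarrow <- (hi - lo) < 4.5 * step
  lo[tooNarrow] <- centers[tooNarrow] - 2.5 * step
  hi[tooNarrow] <- centers[tooNarrow] + 2.5 * step
  models <- vector("list", length(centers))
  for (pass in seq_len(max(1L, as.integer(iterations)))) {
    for (j in seq_along(centers)) {
      others <- 0
      for (m in models[-j])
        if (!is.null(m)) others <- others + evaluatePeak(m, q)
      resid_prof <- Profile1D(q, profile@intensity - others,
                              meta = profile@meta)
      win <- c(lo[j], hi[j])
      inits <- if (is.null(models[[j]])) {
        hw <- (hi[j] - lo[j]) / 2
        list(list(q1 = centers[j]),
             list(q1 = centers[j], h = hw / 4),
             list(q1 = centers[j], h = hw * 2))
      } else {
        list(list(q1 = models[[j]]@q1, h = models[[j]]@h,
                  amplitude = models[[j]]@amplitude))
      }
      for (ini in inits) {
        fit <- tryCatch(withCallingHandlers(
          fitPeak(resid_prof, win, kind = kind, initial = ini),
          warning = function(w) invokeRestart("muffleWarning")),
          error = function(e) NULL)
        if (!is.null(fit)) { models[[j]] <- fit; break }
      }
    }
    if (length(centers) == 1L) break
  }
  models <- Filter(Negate(is.null), models)
  if (!length(models))
    stop("no peak could be fitted")
  models[order(vapply(models, peakCenter, numeric(1)))]
}

#' Export a peak table
#'
#' @param models list of [PeakModel-class] objects.
#' @return data.frame with columns kind, q1, h, amplitude,
#'   centerUncertainty, widthUncertainty, converged.
#' @export
peakTable <- function(models) {
  do.call(rbind, lapply(models, function(m) data.frame(
    kind = m@kind, q1 = m@q1, h = m@h, amplitude = m@amplitude,
    centerUncertainty = m@centerUncertainty,
    widthUncertainty = m@widthUncertainty, converged = m@converged)))
}
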