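# Canonical internal q unit is inverse Angstrom (the unit of every measured
# peak position); spacings are reported in nm. All unit conversion funnels
# through convertQ().

.Q_UNITS <- c("inverse_angstrom", "inverse_nanometer")

#' Convert momentum-transfer values between units
#'
#' The only supported units are inverse Angstrom and inverse nanometer;
#' A^-1 -> nm^-1 multiplies q by exactly 10. Conversion is an involution:
#' converting there and back is the identity.
#'
#' @param q numeric momentum-transfer values.
#' @param from,to source and target unit, `"inverse_angstrom"` or
#'   `"inverse_nanometer"`.
#' @return numeric vector in the target unit.
#' @examples
#' convertQ(0.1, "inverse_angstrom", "inverse_nanometer") # 1
#' @export
convertQ <- function(q, from = "inverse_angstrom",
                     to = "inverse_angstrom") {
  from <- match.arg(from, .Q_UNITS)
  to <- match.arg(to, .Q_UNITS)
  if (from == to) return(q)
  if (from == "inverse_angstrom") q * 10 else q / 10
}

#' Read a 1D scattering profile from delimited text
#'
#' Accepts 2- or 3-column plain text (q, intensity, optional uncertainty),
#' whitespace- or comma-delimited, with '#' comment lines. Header comment
#' lines of the form `# key: value` are parsed into profile metadata. The
#' returned profile is always in internal units of inverse Angstrom.
#'
#' @param path file path.
#' @param qUnit unit of the q column in the file.
#' @return a [Profile1D-class] object (q in inverse Angstrom).
#' @seealso [writeProfile()]
#' @export
readProfile <- function(path, qUnit = c("inverse_angstrom",
                                        "inverse_nanometer")) {
  qUnit <- match.arg(qUnit)
  if (!file.exists(path))
    stop("profile file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  meta <- list()
  is_comment <- grepl("^\\s*#", lines)
  for (cl in lines[is_comment]) {
    m <- regmatches(cl, regexec("^\\s*#\\s*([^:]+?)\\s*:\\s*(.*)$", cl))[[1]]
    if (length(m) == 3L) meta[[m[2]]] <- m[3]
  }
  keep <- which(!is_comment & nzchar(trimws(lines)))
  if (!length(keep)) stop("no data rows in ", path)
  rows <- lapply(keep, function(i) {
    fields <- strsplit(trimws(lines[i]), "[,[:space:]]+")[[1]]
    vals <- suppressWarnings(as.numeric(fields))
    if (anyNA(vals) || !length(vals) %in% 2:3)
      stop(sprintf("cannot parse numeric row at line %d of %s", i, path))
    vals
  })
  ncols <- unique(lengths(rows))
  if (length(ncols) != 1L)
    stop("inconsistent column count in ", path)
  m <- do.call(rbind, rows)
  q <- convertQ(m[, 1], from = qUnit, to = "inverse_angstrom")
  if (is.unsorted(q, strictly = TRUE))
    stop("q column must be strictly increasing in ", path)
  Profile1D(q = q, intensity = m[, 2],
            sigma = if (ncols == 3L) m[, 3] else NULL, meta = meta)
}

#' Write a 1D scattering profile as delimited text
#'
#' Metadata are written as `# key: value` header lines; data follow as 2 or
#' 3 whitespace-separated columns at full double precision, q in the
#' requested unit.
#'
#' @param x a [Profile1D-class] object.
#' @param path output file path.
#' @param qUnit unit for the q column.
#' @return `path`, invisibly.
#' @export
writeProfile <- function(x, path, qUnit = c("inverse_angstrom",
                                            "inverse_nanometer")) {
  stopifnot(is(x, "Profile1D"))
  qUnit <- match.arg(qUnit)
  hdr <- c(sprintf("# q_unit: %s", qUnit),
           if (length(x@meta))
             sprintf("# %s: %s", names(x@meta),
                     vapply(x@meta, as.character, character(1))))
  q <- convertQ(x@q, from = "inverse_angstrom", to = qUnit)
  cols <- if (length(x@sigma))
    sprintf("%.17g %.17g %.17g", q, x@intensity, x@sigma)
  else sprintf("%.17g %.17g", q, x@intensity)
  writeLines(c(hdr, cols), path)
  invisible(path)
}

#' Restrict a profile to a q window
#'
#' @param x a [Profile1D-class] object.
#' @param qmin,qmax window bounds (inverse Angstrom), inclusive.
#' @return a [Profile1D-class] object covering a subset of the original
#'   q range.
#' @export
windowProfile <- function(x, qmin = -Inf, qmax = Inf) {
  stopifnot(is(x, "Profile1D"))
  keep <- x@q >= qmin & x@q <= qmax
  if (sum(keep) < 2L)
    stop("window [", qmin, ", ", qmax, "] keeps fewer than 2 points")
  Profile1D(q = x@q[keep], intensity = x@intensity[keep],
            sigma = if (length(x@sigma)) x@sigma[keep] else NULL,
            meta = x@meta)
}

#' Subtract a smooth background from a profile
#'
#' Fits a background model by least squares over the union of user-supplied
#' peak-free q windows, evaluates it on the full grid and subtracts it.
#' Resulting intensities may be negative; no clipping is applied. The
#' power-law model I = A * q^-p (the typical SAXS decay, and the default)
#' is fitted as a linear model in log-log space and therefore requires
#' positive intensities inside the windows.
#'
#' @param x a [Profile1D-class] object.
#' @param peakFreeWindows list of length-2 numeric vectors, q intervals
#'   (inverse Angstrom) that contain no Bragg peaks; each must cover at
#'   least 2 profile points.
#' @param model `"power_law"`, `"linear"` or `"constant"`.
#' @return a [Profile1D-class] object with the background removed; the
#'   fitted coefficients are recorded in `profileMeta(x)$background`.
#' @examples
#' p <- Profile1D(q = seq(0.05, 0.6, by = 0.005),
#'                intensity = rep(2, 111))
#' b <- subtractBackground(p, list(c(0.05, 0.1)), model = "constant")
#' all(abs(intensityValues(b)) < 1e-12)
#' @export
subtractBackground <- function(x, peakFreeWindows,
                               model = c("power_law", "linear",
                                         "constant")) {
  stopifnot(is(x, "Profile1D"))
  model <- match.arg(model)
  if (!is.list(peakFreeWindows) || !length(peakFreeWindows))
    stop("peakFreeWindows must be a non-empty list of q intervals")
  inwin <- rep(FALSE, length(x@q))
  for (w in peakFreeWindows) {
    if (length(w) != 2L) stop("each window must be a length-2 interval")
    sel <- x@q >= min(w) & x@q <= max(w)
    if (sum(sel) < 2L)
      stop(sprintf("window [%g, %g] contains fewer than 2 points",
                   min(w), max(w)))
    inwin <- inwin | sel
  }
  qw <- x@q[inwin]; iw <- x@intensity[inwin]
  bg <- switch(model,
    constant = {
      a <- mean(iw)
      list(eval = function(q) rep(a, length(q)), coef = c(level = a))
    },
    linear = {
      fit <- stats::lm(iw ~ qw)
      cf <- stats::coef(fit)
      list(eval = function(q) cf[1] + cf[2] * q,
           coef = c(intercept = unname(cf[1]), slope = unname(cf[2])))
    },
    power_law = {
      if (any(iw <= 0))
        stop("power_law background requires positive intensities ",
             "inside every window")
      fit <- stats::lm(log(iw) ~ log(qw))
      cf <- stats::coef(fit)
      A <- exp(unname(cf[1])); p <- -unname(cf[2])
      list(eval = function(q) A * q^(-p), coef = c(A = A, p = p))
    })
  meta <- x@meta
  meta$background <- list(model = model, coef = bg$coef)
  Profile1D(q = x@q, intensity = x@intensity - bg$eval(x@q),
            sigma = if (length(x@sigma)) x@sigma else NULL, meta = meta)
}
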