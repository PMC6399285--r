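# shared fixtures built in code

# exact square-lattice peak positions (A^-1) for a spacing in nm
squarePositions <- function(d_nm, moduli) 2 * pi / (10 * d_nm) * moduli

# write a small profile file and return its path
writeTempProfile <- function(lines) {
  path <- tempfile(fileext = ".dat")
  writeLines(lines, path)
  path
}

# brute-force minimal wheel sector covering a set of angles (degrees)
bruteFaceSector <- function(angles) {
  angles <- sort(unique(angles %% 360))
  if (length(angles) < 2) return(0)
  best <- Inf
  for (start in angles) {
    ext <- max((angles - start) %% 360)
    best <- min(best, ext)
  }
  best
}

# independent brute-force enumeration used as the oracle: enumerate all
# index tuples up to a generous bound, apply the phase's selection rule,
# deduplicate moduli, truncate at the cutoff
bruteModuli <- function(phase, cutoff) {
  bound <- cutoff + 1L
  if (phase == "lamellar") return(as.numeric(seq_len(cutoff)))
  if (phase %in% c("square_columnar", "hexagonal_columnar")) {
    g <- expand.grid(h = 0:bound, k = 0:bound)
    g <- g[g$h + g$k > 0, ]
    m <- if (phase == "square_columnar") sqrt(g$h^2 + g$k^2) else
      sqrt(g$h^2 + g$h * g$k + g$k^2)
    return(sort(unique(round(m[m <= cutoff + 1e-9], 9))))
  }
  g <- expand.grid(h = 0:bound, k = 0:bound, l = 0:bound)
  g <- g[g$h + g$k + g$l > 0, ]
  allowed <- apply(g, 1, function(r) {
    r <- as.numeric(r)
    if (any(r == 0)) sum(r[r != 0]) %% 2 == 0 else TRUE
  })
  m <- sqrt(rowSums(g^2))[allowed]
  sort(unique(round(m[m <= cutoff + 1e-9], 9)))
}

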