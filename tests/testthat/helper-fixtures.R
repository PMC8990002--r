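# Shared fixtures, built in code.

PROTON <- 1.007276467
HEXNAC <- 203.0793724
HEX <- 162.0528234

# Brute-force isotope-pattern oracle: multiply the isotopologue
# polynomial one atom at a time (no squaring shortcut, no truncation
# tricks beyond the requested length).
bruteIsotopePattern <- function(counts, nPeaks) {
  abund <- list(
    C = c(0.9893, 0.0107), H = c(0.999885, 0.000115),
    N = c(0.99636, 0.00364), O = c(0.99757, 0.00038, 0.00205),
    S = c(0.9499, 0.0075, 0.0425, 0.0, 0.0001), P = 1.0)
  p <- 1.0
  mul <- function(a, b) {
    out <- numeric(min(nPeaks, length(a) + length(b) - 1L))
    for (i in seq_along(a)) for (j in seq_along(b)) {
      k <- i + j - 1L
      if (k <= length(out)) out[k] <- out[k] + a[i] * b[j]
    }
    out
  }
  for (el in names(counts)) {
    for (a in seq_len(counts[[el]])) p <- mul(p, abund[[el]])
  }
  length(p) <- nPeaks
  p[is.na(p)] <- 0
  p / max(p)
}

# A clean glycopeptide MS2 spectrum: oxonium ions, the full core Y
# ladder at 1+, optional extra Y steps and b/y peaks.
ladderSpectrum <- function(pepMass, charge = 1L,
                           yIntensity = c(50, 95, 70, 55, 45, 40),
                           extraY = numeric(0), extra = NULL,
                           oxonium = TRUE, glycanMass = 892.3172,
                           rt = 300) {
  off <- c(0, HEXNAC, 2 * HEXNAC, HEX + 2 * HEXNAC,
           2 * HEX + 2 * HEXNAC, 3 * HEX + 2 * HEXNAC)
  mz <- (pepMass + off + PROTON)
  it <- yIntensity
  if (oxonium) {
    mz <- c(mz, 204.0867, 138.0549, 366.1395)
    it <- c(it, 100, 30, 60)
  }
  if (length(extraY)) {
    mz <- c(mz, pepMass + extraY + PROTON)
    it <- c(it, rep(30, length(extraY)))
  }
  if (!is.null(extra)) {
    mz <- c(mz, extra$mz)
    it <- c(it, extra$intensity)
  }
  ms2Spectrum("fix1", (pepMass + glycanMass + charge * PROTON) / charge,
              charge, rt, mz, it)
}

# Small deterministic simulated run shared across tests.
smallRun <- function(seed = 7, ...) {
  simulateRun(simConfig(seed = seed, nPeptides = 4L,
                        glycansPerSite = 2L, scansPerGlycoform = 2L,
                        noisePeaks = 5L, ...))
}
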