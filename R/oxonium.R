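# Oxonium-ion screening: glycopeptide spectra are recognised by their
# low-mass glycan reporter ions before any further processing.

#' Default oxonium ion list
#'
#' Diagnostic low-mass glycan reporter ions used to screen MS2 scans for
#' glycopeptide character: the HexNAc fragment ladder, Hex, HexHexNAc,
#' NeuAc and NeuGc (with water losses) and phosphorylated hexose.  The
#' list is a configurable screening set, not an exhaustive catalogue.
#'
#' @return `data.frame` with columns `name` and `mz`.
#' @examples
#' defaultOxoniumList()
#' @export
defaultOxoniumList <- function() {
  data.frame(
    name = c("HexNAc-C2H6O3", "HexNAc-CH6O3", "HexNAc-2H2O-CH2O",
             "HexNAc-2H2O", "HexNAc-H2O", "HexNAc",
             "Hex", "HexHexNAc",
             "NeuAc-H2O", "NeuAc", "NeuGc-H2O", "NeuGc",
             "PhosphoHex"),
    mz = c(126.0550, 138.0549, 144.0655, 168.0655, 186.0761, 204.0867,
           163.0601, 366.1395,
           274.0921, 292.1027, 290.0870, 308.0976,
           243.0269),
    stringsAsFactors = FALSE)
}

#' Screen an MS2 spectrum for glycopeptide character
#'
#' A spectrum is treated as a glycopeptide spectrum when at least
#' `minCount` distinct oxonium list entries (default 3, i.e. more than
#' two) are matched within the tolerance.
#'
#' @param s An [Ms2Spectrum-class].
#' @param oxonium Oxonium table as from [defaultOxoniumList()].
#' @param minCount Minimum number of distinct matched entries.
#' @param tolPpm Matching half-window, ppm.
#' @return Logical scalar.
#' @export
screenOxonium <- function(s, oxonium = defaultOxoniumList(),
                          minCount = 3L, tolPpm = 20) {
  stopifnot(tolPpm > 0)
  if (!length(s@mz)) return(FALSE)
  hit <- vapply(oxonium$mz, function(m)
    .hasPeak(s@mz, m, tolPpm), logical(1))
  sum(hit) >= minCount
}

# TRUE if any value in sorted vector mz lies within tolPpm of target.
.hasPeak <- function(mz, target, tolPpm) {
  dm <- target * tolPpm * 1e-6
  hi <- findInterval(target + dm, mz)
  lo <- findInterval(target - dm, mz)
  hi > lo
}

# Indices of peaks within tolPpm of target (sorted mz).
.peaksNear <- function(mz, target, tolPpm) {
  dm <- target * tolPpm * 1e-6
  lo <- findInterval(target - dm, mz)
  hi <- findInterval(target + dm, mz)
  if (hi > lo) (lo + 1L):hi else integer(0)
}
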