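# Peptide-backbone mass derivation from the pentasaccharide-core Y-ion
# ladder, and generation of in-silico deglycosylated spectra.

# Glycan-part masses of the six core Y ions, Y0 .. Y-Hex3HexNAc2,
# relative to the bare peptide.
coreYOffsets <- function() {
  m <- monosaccharideMasses()
  c(Y0 = 0,
    Y1 = m[["HexNAc"]],
    Y2 = 2 * m[["HexNAc"]],
    Y3 = m[["Hex"]] + 2 * m[["HexNAc"]],
    Y4 = 2 * m[["Hex"]] + 2 * m[["HexNAc"]],
    Y5 = 3 * m[["Hex"]] + 2 * m[["HexNAc"]])
}

#' Match the N-glycan core Y-ion ladder in an MS2 spectrum
#'
#' Searches a glycopeptide spectrum for the pentasaccharide-core Y-ion
#' ladder (Y0, Y-HexNAc1, Y-HexNAc2, Y-Hex1HexNAc2, Y-Hex2HexNAc2,
#' Y-Hex3HexNAc2) at charges 1 to the precursor charge.  Every peak is
#' treated as a possible core ion at every charge; the implied peptide
#' masses are clustered within the tolerance and clusters supported by at
#' least `minCoreIons` distinct core ions become backbone candidates.
#' Isotopologue peaks of matched ions are folded into the match.
#'
#' Candidates are sorted by the relative intensity of their Y1
#' (peptide+HexNAc) ion; at most `maxCandidates` are kept, and when the
#' best candidate's Y1 relative intensity exceeds `y1Dominance` only that
#' candidate is retained.
#'
#' @param s An [Ms2Spectrum-class] that passed oxonium screening.
#' @param tolPpm Fragment tolerance, ppm.
#' @param minCoreIons Minimum distinct core ions per candidate.
#' @param requireY2 Drop candidates without a Y2 ion (guards against
#'   mistyping small glycans such as single GlcNAc); set `FALSE`
#'   together with a lower `minCoreIons` to search small glycans.
#' @param maxCandidates Candidates retained per spectrum.
#' @param y1Dominance Y1 relative-intensity level above which only the
#'   top candidate is kept.
#' @param massRange Plausible peptide neutral-mass bounds, Da.
#' @return List of candidates, each a list with elements `pepMass`,
#'   `ions` (data.frame `ion`, `charge`, `peak`, `mz`, `intensity`),
#'   `isotopePeaks` (integer indices), `y1RelInt` and `score`.
#' @export
matchCoreLadder <- function(s, tolPpm = 20, minCoreIons = 3L,
                            requireY2 = TRUE, maxCandidates = 5L,
                            y1Dominance = 0.9,
                            massRange = c(600, 4500)) {
  off <- coreYOffsets()
  z <- s@precursorCharge
  prot <- massConstants[["proton"]]
  if (!length(s@mz)) return(list())
  hyp <- list()
  for (c in seq_len(z)) {
    neutral <- s@mz * c - c * prot
    for (k in seq_along(off)) {
      P <- neutral - off[k]
      keep <- which(P >= massRange[1] & P <= massRange[2])
      if (length(keep))
        hyp[[length(hyp) + 1L]] <- data.frame(
          P = P[keep], ion = names(off)[k], charge = c, peak = keep)
    }
  }
  if (!length(hyp)) return(list())
  hyp <- do.call(rbind, hyp)
  hyp <- hyp[order(hyp$P), , drop = FALSE]
  # single-linkage clustering of implied peptide masses
  tolDa <- (hyp$P + max(off)) * tolPpm * 1e-6
  newGrp <- c(TRUE, diff(hyp$P) > tolDa[-1])
  hyp$grp <- cumsum(newGrp)
  base <- max(s@intensity)
  cands <- list()
  for (g in split(hyp, hyp$grp)) {
    ions <- unique(g$ion)
    if (length(ions) < minCoreIons) next
    if (requireY2 && !("Y2" %in% ions)) next
    # one peak per (ion, charge); intensity from the spectrum
    g <- g[!duplicated(g[c("ion", "charge")]), , drop = FALSE]
    g$mz <- s@mz[g$peak]
    g$intensity <- s@intensity[g$peak]
    pepMass <- stats::weighted.mean(g$P, g$intensity)
    isoIdx <- .isotopeIndices(s, g$peak, g$charge, tolPpm)
    y1 <- g$intensity[g$ion == "Y1"]
    y1Rel <- if (length(y1)) max(y1) / base else 0
    cands[[length(cands) + 1L]] <- list(
      pepMass = pepMass,
      ions = g[c("ion", "charge", "peak", "mz", "intensity")],
      isotopePeaks = isoIdx,
      y1RelInt = y1Rel,
      score = length(ions) + sum(g$intensity) / base)
  }
  if (!length(cands)) return(list())
  ord <- order(-vapply(cands, `[[`, numeric(1), "y1RelInt"),
               -vapply(cands, function(x) length(unique(x$ions$ion)),
                       numeric(1)),
               vapply(cands, `[[`, numeric(1), "pepMass"))
  cands <- cands[ord]
  if (cands[[1]]$y1RelInt > y1Dominance) cands <- cands[1]
  else if (length(cands) > maxCandidates)
    cands <- cands[seq_len(maxCandidates)]
  cands
}

# Peaks at +1/+2 isotopologue offsets of the given matched peaks.
.isotopeIndices <- function(s, peaks, charges, tolPpm, nIso = 2L) {
  out <- integer(0)
  for (i in seq_along(peaks)) {
    for (j in seq_len(nIso)) {
      t <- s@mz[peaks[i]] + j * massConstants[["neutron"]] / charges[i]
      out <- c(out, .peaksNear(s@mz, t, tolPpm))
    }
  }
  unique(out)
}

#' Strip glycan-derived peaks and rewrite the precursor
#'
#' Produces the in-silico deglycosylated spectrum for one core-ladder
#' candidate: removes (i) oxonium-list peaks, (ii) the candidate's
#' matched core Y peaks and their isotopologues, and (iii) iteratively,
#' any higher-m/z peak whose distance to an already-matched Y ion equals
#' a monosaccharide residue mass at any charge up to the precursor
#' charge (monosaccharide stepping removal).  The precursor is rewritten
#' to the m/z of peptide+HexNAc at the original charge, so that the
#' downstream search can consider (b/y + HexNAc) fragment ions.
#'
#' @param s Source [Ms2Spectrum-class].
#' @param cand One candidate from [matchCoreLadder()].
#' @param tolPpm Fragment tolerance, ppm.
#' @param oxonium Oxonium table used for removal.
#' @return An [Ms2Spectrum-class] with surviving peaks, rewritten
#'   precursor, and scan id `"<source>|pep=<mass>"`.
#' @export
stripAndRewrite <- function(s, cand, tolPpm = 20,
                            oxonium = defaultOxoniumList()) {
  prot <- massConstants[["proton"]]
  z <- s@precursorCharge
  drop <- unlist(lapply(oxonium$mz, function(m)
    .peaksNear(s@mz, m, tolPpm)))
  drop <- c(drop, cand$ions$peak, cand$isotopePeaks)
  # stepping removal above matched Y ions
  monos <- monosaccharideMasses()
  matchedY <- sort(unique(cand$pepMass + coreYOffsets()[
    match(cand$ions$ion, names(coreYOffsets()))]))
  cap <- precursorMass(s) + 1
  frontier <- matchedY
  known <- matchedY
  while (length(frontier)) {
    nxt <- numeric(0)
    for (g in monos) {
      for (Ym in frontier) {
        Ynew <- Ym + g
        if (Ynew > cap) next
        if (any(abs(known - Ynew) < Ynew * tolPpm * 1e-6)) next
        hitIdx <- integer(0)
        for (c in seq_len(z))
          hitIdx <- c(hitIdx,
                      .peaksNear(s@mz, (Ynew + c * prot) / c, tolPpm))
        if (length(hitIdx)) {
          drop <- c(drop, hitIdx,
                    .isotopeIndices(s, hitIdx, rep(1L, length(hitIdx)),
                                    tolPpm))
          nxt <- c(nxt, Ynew)
          known <- c(known, Ynew)
        }
      }
    }
    frontier <- nxt
  }
  keep <- setdiff(seq_along(s@mz), unique(drop))
  newMz <- (cand$pepMass + monos[["HexNAc"]] + z * prot) / z
  ms2Spectrum(
    scanId = sprintf("%s|pep=%.4f", s@scanId, cand$pepMass),
    precursorMz = newMz, precursorCharge = z, rt = s@rt,
    mz = s@mz[keep], intensity = s@intensity[keep])
}

#' In-silico deglycosylation of a whole run
#'
#' Screens every MS2 scan for oxonium ions, matches the core Y-ion
#' ladder, and emits one deglycosylated spectrum per retained backbone
#' candidate, together with a candidate table.
#'
#' @param ms2 List of [Ms2Spectrum-class].
#' @param tolPpm Fragment tolerance, ppm.
#' @param minOxonium Oxonium screening threshold.
#' @param oxonium Oxonium table.
#' @param mgfPath,tablePath Optional output paths for the MGF of
#'   deglycosylated spectra and the TSV candidate table.
#' @param ... Passed to [matchCoreLadder()].
#' @return `list(spectra = list of deglycosylated Ms2Spectrum,
#'   candidates = data.frame(scanId, candidate, pepMass, nIons,
#'   y1RelInt))` with one row per emitted spectrum.
#' @export
deglycosylateRun <- function(ms2, tolPpm = 20, minOxonium = 3L,
                             oxonium = defaultOxoniumList(),
                             mgfPath = NULL, tablePath = NULL, ...) {
  outSpec <- list()
  rows <- list()
  for (s in ms2) {
    if (!screenOxonium(s, oxonium, minOxonium, tolPpm)) next
    cands <- matchCoreLadder(s, tolPpm = tolPpm, ...)
    for (j in seq_along(cands)) {
      d <- stripAndRewrite(s, cands[[j]], tolPpm, oxonium)
      outSpec[[length(outSpec) + 1L]] <- d
      rows[[length(rows) + 1L]] <- data.frame(
        scanId = s@scanId, candidate = j,
        pepMass = cands[[j]]$pepMass,
        nIons = length(unique(cands[[j]]$ions$ion)),
        y1RelInt = cands[[j]]$y1RelInt, stringsAsFactors = FALSE)
    }
  }
  candidates <- if (length(rows)) do.call(rbind, rows) else
    data.frame(scanId = character(0), candidate = integer(0),
               pepMass = numeric(0), nIons = integer(0),
               y1RelInt = numeric(0))
  if (!is.null(mgfPath) && length(outSpec)) writeMgf(outSpec, mgfPath)
  if (!is.null(tablePath))
    utils::write.table(candidates, tablePath, sep = "\t",
                       row.names = FALSE, quote = FALSE)
  list(spectra = outSpec, candidates = candidates)
}
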