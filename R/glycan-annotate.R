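# Precursor monoisotope correction, glycan annotation by database B/Y
# scoring, monosaccharide stepping for modified glycans, and
# glycan-level FDR.

#' Correct a precursor to its monoisotopic mass
#'
#' Tests monoisotope offsets of -2..+2 isotopologue spacings against the
#' MS1 map: for each candidate offset the isotopologue XICs are
#' extracted around the triggering retention time, peaks whose elution
#' profile does not correlate with the anchor isotopologue are
#' discarded as noise, and the surviving envelope is compared by cosine
#' to the theoretical pattern computed from the peptide elements plus
#' the pseudo-glycan simulation of the residual glycan mass.  The
#' offset with the best envelope similarity wins.
#'
#' @param s [Ms2Spectrum-class] (its precursor descriptor is corrected).
#' @param pepMass Identified peptide neutral mass, Da.
#' @param pepElements Elemental composition of the peptide (see
#'   [peptideElements()]).
#' @param ms1 [Ms1Map-class] or `NULL`.
#' @param tolPpm MS1 matching tolerance, ppm.
#' @param offsets Candidate monoisotope offsets (isotopologue units).
#' @param rtHalfWindow RT half-window for XIC extraction, seconds.
#' @param corThreshold Minimum XIC correlation with the anchor for an
#'   isotopologue peak to count.
#' @param nIso Envelope length compared.
#' @return List with `mass` (corrected neutral precursor mass),
#'   `offset`, `similarity`, `corrected` (FALSE when no MS1 evidence
#'   was available and the mass is passed through).
#' @export
correctPrecursor <- function(s, pepMass, pepElements, ms1,
                             tolPpm = 20, offsets = -2:2,
                             rtHalfWindow = 30, corThreshold = 0.7,
                             nIso = 5L) {
  z <- s@precursorCharge
  neutron <- massConstants[["neutron"]]
  prot <- massConstants[["proton"]]
  if (is.null(ms1) || !length(ms1@rt))
    return(list(mass = precursorMass(s), offset = 0L,
                similarity = NA_real_, corrected = FALSE))
  rtRange <- c(s@rt - rtHalfWindow, s@rt + rtHalfWindow)
  best <- NULL
  for (k in offsets) {
    monoMz <- s@precursorMz + k * neutron / z
    monoMass <- monoMz * z - z * prot
    gMass <- monoMass - pepMass
    if (gMass <= 0) next
    theo <- tryCatch(
      isotopePattern(ecSum(pepElements, pseudoGlycanElements(gMass)),
                     nPeaks = nIso)$abundance,
      error = function(e) NULL)
    if (is.null(theo)) next
    xics <- lapply(seq_len(nIso) - 1L, function(j)
      extractXic(ms1, monoMz + j * neutron / z, tolPpm, rtRange))
    env <- vapply(xics, function(x)
      if (nrow(x)) max(x$intensity) else 0, numeric(1))
    if (env[1] <= 0) next
    anchor <- which.max(env)
    keepIso <- vapply(seq_len(nIso), function(j) {
      if (j == anchor) return(TRUE)
      a <- xics[[anchor]]$intensity; b <- xics[[j]]$intensity
      if (sum(b > 0) < 3L || stats::sd(b) == 0 || stats::sd(a) == 0)
        return(env[j] == 0)   # silent channels are fine, noise is not
      stats::cor(a, b) >= corThreshold
    }, logical(1))
    env[!keepIso] <- 0
    sim <- sum(env * theo) / sqrt(sum(env^2) * sum(theo^2))
    if (is.null(best) || sim > best$similarity)
      best <- list(mass = monoMass, offset = as.integer(k),
                   similarity = sim, corrected = TRUE)
  }
  if (is.null(best))
    return(list(mass = precursorMass(s), offset = 0L,
                similarity = NA_real_, corrected = FALSE))
  best
}

#' Score matched glycan fragment ions (Score_Glycan)
#'
#' Sum over matched theoretical B/Y ions of the frequency-weighted
#' relative intensity raised to `alpha`.
#'
#' @param s [Ms2Spectrum-class].
#' @param fragments Fragment table from
#'   [theoreticalGlycanFragments()].
#' @param freq Optional numeric frequencies parallel to `fragments`
#'   rows (floored at 1); `NULL` for unit frequencies.
#' @param alpha Intensity exponent.
#' @param tolPpm Fragment tolerance, ppm.
#' @return List with `score` and `nMatched`.
#' @export
scoreGlycan <- function(s, fragments, freq = NULL, alpha = 0.3,
                        tolPpm = 20) {
  if (is.null(fragments) || !nrow(fragments))
    return(list(score = 0, nMatched = 0L))
  hits <- .matchFragments(s, fragments$mz, tolPpm)
  mIdx <- which(hits$matched)
  if (!length(mIdx)) return(list(score = 0, nMatched = 0L))
  base <- max(s@intensity)
  inten <- s@intensity[hits$peakPer[mIdx]] / base
  f <- if (is.null(freq)) rep(1, length(mIdx)) else
    pmax(1, freq[mIdx])
  list(score = sum((inten / f)^alpha), nMatched = length(mIdx))
}

# Frequencies of each candidate's fragment ions among the other
# candidates' fragment tables (floored at 1).
.glycanIonFrequencies <- function(fragTables, tolPpm) {
  allMz <- sort(unlist(lapply(fragTables, function(t) t$mz)))
  lapply(seq_along(fragTables), function(i) {
    own <- sort(fragTables[[i]]$mz)
    vapply(fragTables[[i]]$mz, function(m) {
      dm <- m * tolPpm * 1e-6
      tot <- sum(allMz >= m - dm & allMz <= m + dm)
      self <- sum(own >= m - dm & own <= m + dm)
      max(1L, tot - self)
    }, numeric(1))
  })
}

#' Annotate a glycan mass by database matching
#'
#' Scores every database entry whose mass lies within the tolerance of
#' the derived glycan mass by matched B/Y ions; the best score wins,
#' ties broken by fewest residues then lexicographic composition.
#'
#' @param s [Ms2Spectrum-class] of the GPSM.
#' @param pepMass Peptide neutral mass.
#' @param glycanMass Derived glycan mass (corrected precursor minus
#'   peptide), Da.
#' @param db Glycan database ([readGlycanDb()]).
#' @param tolDa Glycan-mass candidacy tolerance, Da.
#' @param alpha Intensity exponent.
#' @param tolPpm Fragment tolerance, ppm.
#' @return List with `composition` ([GlycanComposition-class]),
#'   `accession`, `score`, `nMatched`, `route = "database"`; or `NULL`
#'   when no entry is within tolerance (eligible for stepping).
#' @export
annotateFromDb <- function(s, pepMass, glycanMass, db, tolDa = 0.05,
                           alpha = 0.3, tolPpm = 20) {
  cand <- db[abs(db$mass - glycanMass) <= tolDa, , drop = FALSE]
  if (!nrow(cand)) return(NULL)
  fragTables <- lapply(seq_len(nrow(cand)), function(i)
    theoreticalGlycanFragments(cand[i, ], pepMass,
                               maxCharge = s@precursorCharge))
  ok <- !vapply(fragTables, is.null, logical(1))
  cand <- cand[ok, , drop = FALSE]
  fragTables <- fragTables[ok]
  if (!nrow(cand)) return(NULL)
  freqs <- .glycanIonFrequencies(fragTables, tolPpm)
  scores <- lapply(seq_along(fragTables), function(i)
    scoreGlycan(s, fragTables[[i]], freqs[[i]], alpha, tolPpm))
  sc <- vapply(scores, `[[`, numeric(1), "score")
  nres <- vapply(cand$composition, function(x)
    sum(glycanCounts(parseGlycanComposition(x))), numeric(1))
  o <- order(-sc, nres, cand$composition)
  i <- o[1]
  list(composition = parseGlycanComposition(cand$composition[i]),
       accession = cand$accession[i], score = sc[i],
       nMatched = scores[[i]]$nMatched, route = "database")
}

#' Candidate (base composition, moiety mass) pairs for a glycan mass
#'
#' Enumerates database glycans whose subtraction from the observed
#' glycan mass leaves a plausible modification moiety.
#'
#' @param glycanMass Observed glycan mass, Da.
#' @param db Glycan database.
#' @param moietyRange Allowed moiety-mass interval, Da.
#' @return `data.frame(accession, composition, baseMass, moietyMass)`.
#' @export
steppingCandidates <- function(glycanMass, db,
                               moietyRange = c(1, 300)) {
  moiety <- glycanMass - db$mass
  keep <- moiety >= moietyRange[1] & moiety <= moietyRange[2]
  out <- data.frame(accession = db$accession[keep],
                    composition = db$composition[keep],
                    baseMass = db$mass[keep],
                    moietyMass = moiety[keep],
                    stringsAsFactors = FALSE)
  out[order(out$moietyMass), , drop = FALSE]
}

# Count stepping routes: orderings of the gap multiset for which every
# cumulative Y mass is witnessed by a spectrum peak at some charge.
.countRoutes <- function(s, startMass, gaps, tolPpm, maxCharge) {
  prot <- massConstants[["proton"]]
  observed <- function(mass) {
    for (z in seq_len(maxCharge))
      if (.hasPeak(s@mz, (mass + z * prot) / z, tolPpm)) return(TRUE)
    FALSE
  }
  if (!observed(startMass)) return(0L)
  vals <- sort(unique(round(gaps, 6)))
  counts <- vapply(vals, function(v) sum(abs(gaps - v) < 1e-6),
                   integer(1))
  recur <- function(cur, counts) {
    if (all(counts == 0L)) return(1L)
    total <- 0L
    for (i in seq_along(vals)) {
      if (counts[i] == 0L) next
      nxt <- cur + vals[i]
      if (observed(nxt)) {
        counts[i] <- counts[i] - 1L
        total <- total + recur(nxt, counts)
        counts[i] <- counts[i] + 1L
      }
    }
    total
  }
  recur(startMass, counts)
}

#' Deduce a modified glycan by monosaccharide stepping
#'
#' For a glycan mass with no database match, candidate (base
#' composition, moiety) pairs are enumerated by subtracting database
#' glycan masses from the observed mass.  For each candidate the Y-ion
#' series is stepped from Y-Hex(3)HexNAc(2) upward using the candidate's
#' remaining monosaccharide masses plus the moiety as gaps; a route is
#' valid when every cumulative Y ion (through to the intact glycopeptide
#' at any charge, the stepping terminal) is witnessed by a spectrum
#' peak.  A moiety whose gap is not flanked by two consecutive observed
#' Y ions therefore yields no route and is discarded.  The candidate
#' with the maximum number of valid routes is returned.
#'
#' @param s [Ms2Spectrum-class] of the GPSM.
#' @param pepMass Peptide neutral mass, Da.
#' @param glycanMass Observed (corrected) glycan mass, Da.
#' @param db Glycan database.
#' @param tolPpm Fragment tolerance, ppm.
#' @param moietyRange Allowed moiety-mass interval, Da.
#' @return List with `composition` (base, with `moietyMass` set),
#'   `accession`, `moietyMass`, `routeCount`, `route = "stepping"`; or
#'   `NULL` when no candidate has a valid route.
#' @export
monosaccharideStepping <- function(s, pepMass, glycanMass, db,
                                   tolPpm = 20,
                                   moietyRange = c(1, 300)) {
  cand <- steppingCandidates(glycanMass, db, moietyRange)
  if (!nrow(cand)) return(NULL)
  core <- c(Hex = 3, HexNAc = 2)
  monos <- monosaccharideMasses()
  coreMass <- 3 * monos[["Hex"]] + 2 * monos[["HexNAc"]]
  best <- NULL
  for (i in seq_len(nrow(cand))) {
    comp <- parseGlycanComposition(cand$composition[i])
    cnt <- glycanCounts(comp)
    rem <- cnt
    rem[names(core)] <- rem[names(core)] - core[names(core)]
    if (anyNA(rem) || any(rem < 0) ||
        !all(names(core) %in% names(cnt))) next
    gaps <- c(rep(monos[names(rem)], times = rem),
              cand$moietyMass[i])
    routes <- .countRoutes(s, pepMass + coreMass, gaps, tolPpm,
                           s@precursorCharge)
    if (routes >= 1L &&
        (is.null(best) || routes > best$routeCount ||
         (routes == best$routeCount &&
            abs(cand$moietyMass[i]) < abs(best$moietyMass)))) {
      resComp <- glycanComposition(cnt,
                                   moietyMass = cand$moietyMass[i])
      best <- list(composition = resComp,
                   accession = cand$accession[i],
                   moietyMass = cand$moietyMass[i],
                   routeCount = routes, route = "stepping")
    }
  }
  best
}

#' Glycan-level FDR by decoy-spectrum e-values
#'
#' Generates a decoy spectrum for each GPSM (random 1-30 Th fragment
#' shifts), rescores the assigned glycan's fragments against it, fits
#' the linear tail e-value model on the pooled target and decoy scores,
#' and flags GPSMs passing the FDR threshold.
#'
#' @param gpsms `data.frame` with columns `scanId`, `pepMass`,
#'   `composition` (label string) and `glycanScore`.
#' @param spectra Named list of [Ms2Spectrum-class], keyed by scan id.
#' @param db Glycan database (for fragment regeneration); entries not
#'   in the db are fragmented from their composition.
#' @param seed Decoy seed.
#' @param alpha,tolPpm Scoring parameters.
#' @param fdrThreshold Acceptance threshold.
#' @return `gpsms` with `glycanEvalue`, `glycanFdr` and `glycanPass`
#'   columns; with fewer than 10 GPSMs all flags are `NA`
#'   (indeterminate).
#' @export
glycanFdr <- function(gpsms, spectra, db = NULL, seed = 1L,
                      alpha = 0.3, tolPpm = 20, fdrThreshold = 0.01) {
  n <- nrow(gpsms)
  if (n < 10L) {
    gpsms$glycanEvalue <- NA_real_
    gpsms$glycanFdr <- NA_real_
    gpsms$glycanPass <- NA
    return(gpsms)
  }
  decoyScores <- vapply(seq_len(n), function(i) {
    s <- spectra[[gpsms$scanId[i]]]
    if (is.null(s)) return(0)
    frag <- theoreticalGlycanFragments(
      list(composition = sub("[+-][0-9.]+$", "", gpsms$composition[i]),
           topology = ""),
      gpsms$pepMass[i], maxCharge = s@precursorCharge)
    scoreGlycan(makeDecoySpectrum(s, seed), frag, NULL, alpha,
                tolPpm)$score
  }, numeric(1))
  all <- c(gpsms$glycanScore, decoyScores)
  dec <- c(rep(FALSE, n), rep(TRUE, n))
  model <- fitEvalueModel(all, dec)
  if (!model$valid) {
    gpsms$glycanEvalue <- NA_real_
    gpsms$glycanFdr <- NA_real_
    gpsms$glycanPass <- NA
    return(gpsms)
  }
  ev <- evalueOf(model, all)
  o <- order(ev)
  nd <- cumsum(dec[o]); nt <- cumsum(!dec[o])
  fdr <- 2 * nd / (nd + nt)
  fdr <- rev(cummin(rev(fdr)))
  fdrAll <- numeric(2 * n); fdrAll[o] <- fdr
  gpsms$glycanEvalue <- ev[seq_len(n)]
  gpsms$glycanFdr <- fdrAll[seq_len(n)]
  gpsms$glycanPass <- gpsms$glycanFdr < fdrThreshold
  gpsms
}

#' Classify a glycan composition
#'
#' Three-way classification used for reporting: truncated
#' (Hex<4, HexNAc<3, Fuc<2, no sialic acid), oligo-mannose (Hex>3,
#' HexNAc=2, Fuc<2, no sialic acid) and complex/hybrid (everything
#' else), with complex/hybrid subdivided by fucose and sialic-acid
#' content.
#'
#' @param comp [GlycanComposition-class] (or coercible); the moiety is
#'   ignored for classification.
#' @return List with `class` and, for complex/hybrid, `subgroup` in
#'   `{"fucose- and sialic acid-free", "fucosylated, sialic acid-free",
#'   "sialylated, fucose-free", "fucosylated and sialylated"}`.
#' @export
classifyGlycan <- function(comp) {
  comp <- as.glycanComposition(comp)
  cnt <- c(Hex = 0, HexNAc = 0, Fuc = 0, NeuAc = 0, NeuGc = 0)
  cnt[names(comp@counts)[names(comp@counts) %in% names(cnt)]] <-
    comp@counts[names(comp@counts) %in% names(cnt)]
  sial <- cnt[["NeuAc"]] + cnt[["NeuGc"]]
  if (cnt[["Hex"]] < 4 && cnt[["HexNAc"]] < 3 && cnt[["Fuc"]] < 2 &&
      sial == 0)
    return(list(class = "truncated", subgroup = NA_character_))
  if (cnt[["Hex"]] > 3 && cnt[["HexNAc"]] == 2 && cnt[["Fuc"]] < 2 &&
      sial == 0)
    return(list(class = "oligo-mannose", subgroup = NA_character_))
  sub <- if (cnt[["Fuc"]] == 0 && sial == 0)
    "fucose- and sialic acid-free"
  else if (cnt[["Fuc"]] > 0 && sial == 0)
    "fucosylated, sialic acid-free"
  else if (cnt[["Fuc"]] == 0) "sialylated, fucose-free"
  else "fucosylated and sialylated"
  list(class = "complex/hybrid", subgroup = sub)
}
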