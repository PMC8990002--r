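# Spectrum expansion: conserved peptide fragmentation patterns are
# learned from identified glycopeptide spectra and used to match
# unidentified spectra of the same backbone within a retention-time
# window, with decoy spectra and linear tail-fit e-values for FDR
# control.

#' Theoretical peptide fragment ions
#'
#' b/y series at charges 1-2 with ammonia/water-loss variants and +1/+2
#' isotopologue peaks; m/z by the proton convention.  When `hexnacSite`
#' is given, b/y ions covering that residue are also emitted with a
#' HexNAc stub (+203.0794), the ion type tagged `+HexNAc`.
#'
#' @param sequence Peptide string.
#' @param modPos,modMass Positioned modifications.
#' @param charges Fragment charges considered.
#' @param losses Include -NH3/-H2O variants.
#' @param nIsotopes Extra isotopologue peaks per ion (0 = mono only).
#' @param hexnacSite Optional 1-based sequon position for +HexNAc stub
#'   variants.
#' @return `data.frame(type, series, index, loss, charge, iso, mz)`;
#'   `type` collapses charge and isotopologue (e.g. `"y5-NH3"`).
#' @examples
#' head(theoreticalPeptideFragments("PEPTIDE"))
#' @export
theoreticalPeptideFragments <- function(sequence, modPos = integer(0),
                                        modMass = numeric(0),
                                        charges = 1:2, losses = TRUE,
                                        nIsotopes = 2L,
                                        hexnacSite = NA) {
  r <- residueMasses(sequence, modPos, modMass)
  n <- length(r)
  prot <- massConstants[["proton"]]
  water <- massConstants[["water"]]
  bNeutral <- cumsum(r)[-n]
  yNeutral <- rev(cumsum(rev(r)))[-1] + water
  ions <- rbind(
    data.frame(series = "b", index = seq_len(n - 1L), neutral = bNeutral),
    data.frame(series = "y", index = seq_len(n - 1L),
               neutral = rev(yNeutral)))
  # y_i covers the C-terminal i residues
  ions$covers <- ifelse(ions$series == "b", NA, NA)
  lossTab <- if (losses)
    c(none = 0, `-NH3` = -massConstants[["ammonia"]],
      `-H2O` = -water) else c(none = 0)
  hexnac <- monosaccharideMasses()[["HexNAc"]]
  stub <- c(0)
  out <- list()
  for (li in seq_along(lossTab)) {
    tag <- names(lossTab)[li]
    tagStr <- if (tag == "none") "" else tag
    for (st in if (!is.na(hexnacSite)) c(0, 1) else 0) {
      d <- ions
      if (st == 1) {
        keep <- (d$series == "b" & d$index >= hexnacSite) |
          (d$series == "y" & d$index >= (n - hexnacSite + 1L))
        d <- d[keep, , drop = FALSE]
        if (!nrow(d)) next
      }
      for (z in charges) {
        for (iso in 0:nIsotopes) {
          mz <- (d$neutral + lossTab[li] + st * hexnac + z * prot +
                   iso * massConstants[["neutron"]]) / z
          out[[length(out) + 1L]] <- data.frame(
            type = paste0(d$series, d$index, tagStr,
                          if (st == 1) "+HexNAc" else ""),
            series = d$series, index = d$index,
            loss = tag, charge = z, iso = iso, mz = mz,
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Extract the fragmentation pattern of a PSM
#'
#' Matches the spectrum to the peptide's theoretical fragment ions, sums
#' intensity per ion type over charge states and isotopologues, and
#' normalises against the maximum.
#'
#' @param s [Ms2Spectrum-class].
#' @param sequence,modPos,modMass Peptide and modifications.
#' @param tolPpm Fragment tolerance, ppm.
#' @return A [FragmentationPattern-class] (empty if nothing matches).
#' @export
extractPattern <- function(s, sequence, modPos = integer(0),
                           modMass = numeric(0), tolPpm = 20) {
  frag <- theoreticalPeptideFragments(sequence, modPos, modMass)
  hits <- .matchFragments(s, frag$mz, tolPpm)
  if (!any(hits$matched))
    return(new("FragmentationPattern", support = 1L, meanRt = s@rt))
  mIdx <- which(hits$matched)
  inten <- s@intensity[hits$peakPer[mIdx]]
  summed <- tapply(inten, frag$type[mIdx], sum)
  vals <- as.numeric(summed) / max(summed)
  names(vals) <- names(summed)
  new("FragmentationPattern", values = vals, support = 1L,
      meanRt = s@rt)
}

#' Average fragmentation pattern over PSMs of one backbone
#'
#' Per-type arithmetic mean (absent type contributes 0), renormalised to
#' max 1; the mean retention time of the contributing PSMs is recorded
#' for the expansion retention-time window.
#'
#' @param patterns Non-empty list of [FragmentationPattern-class].
#' @return Averaged [FragmentationPattern-class].
#' @export
averagePattern <- function(patterns) {
  if (!length(patterns)) stop("no patterns to average", call. = FALSE)
  keys <- unique(unlist(lapply(patterns, function(p) names(p@values))))
  if (!length(keys))
    return(new("FragmentationPattern", support = length(patterns),
               meanRt = mean(vapply(patterns, function(p) p@meanRt,
                                    numeric(1)), na.rm = TRUE)))
  acc <- stats::setNames(numeric(length(keys)), keys)
  for (p in patterns) acc[names(p@values)] <- acc[names(p@values)] +
      p@values
  acc <- acc / length(patterns)
  acc <- acc / max(acc)
  new("FragmentationPattern", values = acc,
      support = sum(vapply(patterns, function(p) p@support, integer(1))),
      meanRt = mean(vapply(patterns, function(p) p@meanRt, numeric(1)),
                    na.rm = TRUE))
}

#' Cosine similarity of two fragmentation patterns
#'
#' Standard cosine over the union of ion types; defined as 0 when either
#' pattern is empty.
#'
#' @param p1,p2 [FragmentationPattern-class] objects.
#' @return Numeric in `[0, 1]`.
#' @export
cosineSimilarity <- function(p1, p2) {
  if (!length(p1@values) || !length(p2@values)) return(0)
  keys <- union(names(p1@values), names(p2@values))
  a <- stats::setNames(numeric(length(keys)), keys)
  b <- a
  a[names(p1@values)] <- p1@values
  b[names(p2@values)] <- p2@values
  sum(a * b) / sqrt(sum(a^2) * sum(b^2))
}

#' Fragment-ion frequency index
#'
#' Counts, for any query m/z, how many theoretical b/y ions of *other*
#' peptides in the search space fall within the mass tolerance window.
#' The count is floored at 1 so it can divide intensities.
#'
#' @param index Peptide index ([digestProteome()]).
#' @param tolPpm Window half-width, ppm.
#' @param massRange Optional peptide-mass restriction (the observed
#'   backbone-mass range of the run).
#' @return A frequency index object for [frequencyLookup()].
#' @export
buildFrequencyIndex <- function(index, tolPpm = 20, massRange = NULL) {
  if (!is.null(massRange))
    index <- index[index$mass >= massRange[1] &
                     index$mass <= massRange[2], , drop = FALSE]
  mzs <- list(); ids <- list()
  for (i in seq_len(nrow(index))) {
    fr <- theoreticalPeptideFragments(index$peptide[i],
                                      .splitNum(index$modPos[i]),
                                      .splitNum(index$modMass[i]),
                                      charges = 1:2, losses = FALSE,
                                      nIsotopes = 0L)
    mzs[[i]] <- fr$mz
    ids[[i]] <- rep(paste0(index$peptide[i], "/", index$modPos[i]),
                    nrow(fr))
  }
  mz <- unlist(mzs); id <- unlist(ids)
  o <- order(mz)
  structure(list(mz = mz[o], id = id[o], tolPpm = tolPpm),
            class = "fragmentFrequencyIndex")
}

#' @rdname buildFrequencyIndex
#' @param fi Frequency index.
#' @param mz Query m/z values.
#' @param excludeId Peptide identity (`"<peptide>/<modPos>"`) whose own
#'   ions are not counted.
#' @return Integer vector of frequencies (>= 1).
#' @export
frequencyLookup <- function(fi, mz, excludeId = NULL) {
  vapply(mz, function(m) {
    dm <- m * fi$tolPpm * 1e-6
    lo <- findInterval(m - dm, fi$mz)
    hi <- findInterval(m + dm, fi$mz)
    n <- if (hi > lo) {
      idx <- (lo + 1L):hi
      if (is.null(excludeId)) length(idx)
      else sum(fi$id[idx] != excludeId)
    } else 0L
    max(1L, n)
  }, numeric(1))
}

#' Pattern-aware expansion score of a spectrum against a backbone
#'
#' The match score is the sum of a peptide term and a core term: the
#' peptide term is the pattern cosine (`coefficient`) times the sum of
#' frequency-weighted matched peptide-ion relative intensities raised to
#' `alpha`; the core term is the plain sum of frequency-weighted matched
#' core Y-ion relative intensities.
#'
#' @param s [Ms2Spectrum-class] to score.
#' @param pepRow One peptide-index row (peptide, modPos, modMass, mass).
#' @param avgPattern Averaged backbone [FragmentationPattern-class].
#' @param freqIndex Frequency index from [buildFrequencyIndex()] (or
#'   `NULL` for unit frequencies).
#' @param alpha Intensity exponent of the peptide term.
#' @param tolPpm Fragment tolerance, ppm.
#' @return List with `score`, `scorePeptide`, `scoreCore`,
#'   `coefficient`, `n` (matched peptide ion types), `m` (matched core
#'   ions), `y1Matched`.
#' @export
scoreExpansion <- function(s, pepRow, avgPattern, freqIndex = NULL,
                           alpha = 0.3, tolPpm = 20) {
  obs <- extractPattern(s, pepRow$peptide, .splitNum(pepRow$modPos),
                        .splitNum(pepRow$modMass), tolPpm)
  coeff <- cosineSimilarity(obs, avgPattern)
  base <- if (length(s@intensity)) max(s@intensity) else 1
  pepId <- paste0(pepRow$peptide, "/", pepRow$modPos)
  # peptide term: matched ion types at their base 1+ m/z for frequency
  scPep <- 0; n <- 0L
  if (length(obs@values)) {
    frag <- theoreticalPeptideFragments(pepRow$peptide,
                                        .splitNum(pepRow$modPos),
                                        .splitNum(pepRow$modMass),
                                        charges = 1L, losses = TRUE,
                                        nIsotopes = 0L)
    hits <- .matchFragments(s, frag$mz, tolPpm)
    mIdx <- which(hits$matched)
    if (length(mIdx)) {
      inten <- s@intensity[hits$peakPer[mIdx]] / base
      f <- if (is.null(freqIndex)) rep(1, length(mIdx)) else
        frequencyLookup(freqIndex, frag$mz[mIdx], pepId)
      perType <- tapply(inten / f, frag$type[mIdx], max)
      n <- length(perType)
      scPep <- coeff * sum(as.numeric(perType)^alpha)
    }
  }
  # core term: the six core Y ions at charges 1..z
  prot <- massConstants[["proton"]]
  off <- coreYOffsets()
  m <- 0L; scCore <- 0; y1 <- FALSE
  for (k in seq_along(off)) {
    bestI <- 0
    for (z in seq_len(s@precursorCharge)) {
      t <- (pepRow$mass + off[k] + z * prot) / z
      pk <- .peaksNear(s@mz, t, tolPpm)
      if (length(pk)) bestI <- max(bestI, max(s@intensity[pk]))
    }
    if (bestI > 0) {
      m <- m + 1L
      if (names(off)[k] == "Y1") y1 <- TRUE
      f <- if (is.null(freqIndex)) 1 else
        frequencyLookup(freqIndex, pepRow$mass + off[k] + prot, pepId)
      scCore <- scCore + (bestI / base) / f
    }
  }
  list(score = scPep + scCore, scorePeptide = scPep,
       scoreCore = scCore, coefficient = coeff, n = n, m = m,
       y1Matched = y1)
}

#' Decoy spectrum by random fragment m/z shifts
#'
#' Shifts every fragment m/z by an independent draw from
#' Uniform(1, 30) Th with a random sign, preserving the intensity
#' multiset.  Deterministic for a given (seed, scan id) pair.
#'
#' @param s [Ms2Spectrum-class].
#' @param seed Integer seed.
#' @return Shifted decoy [Ms2Spectrum-class], scan id suffixed
#'   `"|decoy"`.
#' @export
makeDecoySpectrum <- function(s, seed = 1L) {
  n <- length(s@mz)
  if (!n) return(s)
  localSeed <- (as.integer(seed) * 7919L +
                  sum(utf8ToInt(s@scanId) *
                        seq_len(nchar(s@scanId)))) %% .Machine$integer.max
  shift <- withRngSeed(localSeed, {
    stats::runif(n, 1, 30) * sample(c(-1, 1), n, replace = TRUE)
  })
  mz <- s@mz + shift
  flip <- mz < 1
  mz[flip] <- s@mz[flip] + abs(shift[flip])
  ms2Spectrum(paste0(s@scanId, "|decoy"), s@precursorMz,
              s@precursorCharge, s@rt, mz, s@intensity)
}

#' Evaluate code under a temporary RNG seed
#'
#' Runs `expr` with the global RNG seeded to `seed`, restoring the
#' caller's RNG state afterwards.
#'
#' @param seed Integer seed.
#' @param expr Expression to evaluate.
#' @return The value of `expr`.
#' @export
withRngSeed <- function(seed, expr) {
  hadSeed <- exists(".Random.seed", envir = globalenv(),
                    inherits = FALSE)
  old <- if (hadSeed) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (hadSeed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(),
                    inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Linear tail-fit e-value model
#'
#' Fits log10 of the score survival function against score over the
#' upper tail (scores above the 60th percentile of the decoy-score
#' distribution, at least 5 distinct points); the e-value of a score s
#' is `N_total * 10^(a + b s)`, the expected number of random matches
#' scoring at least s.
#'
#' @param scores Numeric scores of all matches, targets and decoys.
#' @param decoy Logical decoy flags (defaults to using all scores for
#'   the tail threshold).
#' @param minPoints Minimum distinct tail points.
#' @return List with `intercept`, `slope`, `n`, `valid`.
#' @export
fitEvalueModel <- function(scores, decoy = NULL, minPoints = 5L) {
  if (length(scores) < 10L)
    stop("need at least 10 scores for a tail fit", call. = FALSE)
  ref <- if (!is.null(decoy) && any(decoy)) scores[decoy] else scores
  cut <- stats::quantile(ref, 0.6, names = FALSE)
  pts <- sort(unique(scores[scores >= cut]))
  if (length(pts) < minPoints)
    pts <- sort(unique(scores), decreasing = TRUE)[
      seq_len(min(length(unique(scores)), max(minPoints, 5L)))]
  surv <- vapply(pts, function(x) mean(scores >= x), numeric(1))
  ok <- surv > 0
  fit <- stats::lm(log10(surv[ok]) ~ pts[ok])
  slope <- unname(stats::coef(fit)[2])
  list(intercept = unname(stats::coef(fit)[1]), slope = slope,
       n = length(scores), valid = is.finite(slope) && slope < 0)
}

#' @rdname fitEvalueModel
#' @param model Fitted model.
#' @param s Scores to convert.
#' @return e-values (expected random matches at or above each score).
#' @export
evalueOf <- function(model, s) {
  pmax(0, model$n * 10^(model$intercept + model$slope * s))
}

#' Target-decoy FDR over expansion matches
#'
#' Matches are ranked by increasing e-value; at each threshold the FDR
#' is `2 N_decoy / (N_decoy + N_target)` over matches at or below it
#' (decoys are counted twice because only half of random matches land
#' on decoys).  Acceptance additionally requires at least 3 matched
#' core ions including Y1, a non-negative implied glycan mass, and a
#' target (non-decoy) match.
#'
#' @param matches `data.frame` with columns `evalue`, `decoy`, `m`,
#'   `y1Matched`, `glycanMass`.
#' @param fdrThreshold Acceptance threshold.
#' @return The input with `fdr` and `accepted` columns, sorted by
#'   e-value.
#' @export
expansionFdr <- function(matches, fdrThreshold = 0.01) {
  if (!nrow(matches)) {
    matches$fdr <- numeric(0); matches$accepted <- logical(0)
    return(matches)
  }
  o <- order(matches$evalue)
  matches <- matches[o, , drop = FALSE]
  nd <- cumsum(matches$decoy)
  nt <- cumsum(!matches$decoy)
  fdr <- ifelse(nd + nt > 0, 2 * nd / (nd + nt), 0)
  matches$fdr <- rev(cummin(rev(fdr)))
  matches$accepted <- matches$fdr < fdrThreshold & !matches$decoy &
    matches$m >= 3L & matches$y1Matched & matches$glycanMass >= -0.01
  rownames(matches) <- NULL
  matches
}

#' Expand one peptide backbone to unidentified spectra
#'
#' Candidate spectra are unassigned scans within the retention-time
#' window of the backbone's mean RT that pass oxonium screening and
#' have a non-negative implied glycan mass; the Y1 (peptide+HexNAc)
#' requirement is enforced at acceptance rather than during candidate
#' selection, so every candidate contributes to the score null
#' distribution.
#' Each candidate is scored against the backbone and against its decoy
#' spectrum; a per-peptide e-value model fitted on the pooled scores
#' converts scores to e-values, and the target-decoy FDR gate selects
#' accepted matches.
#'
#' @param pepRow Peptide-index row (needs `peptide`, `modPos`,
#'   `modMass`, `mass`).
#' @param avgPattern Averaged backbone pattern.
#' @param spectra List of unassigned [Ms2Spectrum-class].
#' @param freqIndex Frequency index or `NULL`.
#' @param rtWindow Retention-time half-window, seconds.
#' @param alpha Intensity exponent.
#' @param tolPpm Fragment tolerance, ppm.
#' @param fdrThreshold Expansion FDR gate.
#' @param seed Decoy-generation seed.
#' @param oxonium Oxonium table for candidate prefiltering.
#' @return `data.frame` of scored matches (targets and decoys) with
#'   `accepted` flags; zero rows when no candidate qualifies.
#' @export
expandPeptide <- function(pepRow, avgPattern, spectra,
                          freqIndex = NULL, rtWindow = 1800,
                          alpha = 0.3, tolPpm = 20,
                          fdrThreshold = 0.01, seed = 1L,
                          oxonium = defaultOxoniumList()) {
  if (!avgPattern@support) stop("pattern without support", call. = FALSE)
  rows <- list()
  for (s in spectra) {
    if (!is.na(avgPattern@meanRt) && !is.na(s@rt) &&
        abs(s@rt - avgPattern@meanRt) > rtWindow) next
    if (precursorMass(s) - pepRow$mass < -0.01) next
    if (!screenOxonium(s, oxonium, tolPpm = tolPpm)) next
    for (dec in c(FALSE, TRUE)) {
      sc <- if (dec)
        scoreExpansion(makeDecoySpectrum(s, seed), pepRow, avgPattern,
                       freqIndex, alpha, tolPpm)
      else scoreExpansion(s, pepRow, avgPattern, freqIndex, alpha,
                          tolPpm)
      rows[[length(rows) + 1L]] <- data.frame(
        scanId = s@scanId, peptide = pepRow$peptide,
        modPos = pepRow$modPos, modMass = pepRow$modMass,
        pepMass = pepRow$mass, rt = s@rt,
        precursorMz = s@precursorMz, charge = s@precursorCharge,
        glycanMass = precursorMass(s) - pepRow$mass,
        score = sc$score, scorePeptide = sc$scorePeptide,
        scoreCore = sc$scoreCore, coefficient = sc$coefficient,
        n = sc$n, m = sc$m, y1Matched = sc$y1Matched, decoy = dec,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) return(.emptyExpansion())
  matches <- do.call(rbind, rows)
  if (nrow(matches) < 10L) {
    matches$evalue <- NA_real_
    matches$fdr <- NA_real_
    matches$accepted <- FALSE
    return(matches)
  }
  model <- fitEvalueModel(matches$score, matches$decoy)
  if (!model$valid) {
    matches$evalue <- NA_real_
    matches$fdr <- NA_real_
    matches$accepted <- FALSE
    return(matches)
  }
  matches$evalue <- evalueOf(model, matches$score)
  expansionFdr(matches, fdrThreshold)
}

.emptyExpansion <- function() {
  data.frame(scanId = character(0), peptide = character(0),
             modPos = character(0), modMass = character(0),
             pepMass = numeric(0), rt = numeric(0),
             precursorMz = numeric(0), charge = integer(0),
             glycanMass = numeric(0), score = numeric(0),
             scorePeptide = numeric(0), scoreCore = numeric(0),
             coefficient = numeric(0), n = integer(0), m = integer(0),
             y1Matched = logical(0), decoy = logical(0),
             evalue = numeric(0), fdr = numeric(0),
             accepted = logical(0))
}
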