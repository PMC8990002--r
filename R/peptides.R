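# Motif-restricted peptide search space and initial peptide-spectrum
# matches: tryptic digestion, external PSM import, and a minimal
# built-in scorer so the pipeline runs without an external engine.

#' Digest a proteome into sequon-bearing tryptic peptides
#'
#' Cleaves after K/R (not before P), allows missed cleavages, applies
#' length and mass bounds, fixes carbamidomethyl on Cys and enumerates
#' up to `maxOxidation` variable Met oxidations.  Only peptides
#' containing at least one N-glycosylation sequon (N-X-S/T/C, X != P)
#' are retained.
#'
#' @param fasta Path to a protein FASTA file, or a named character
#'   vector of protein sequences.
#' @param maxMissedCleavages Maximum missed cleavages.
#' @param lengthRange Peptide length bounds.
#' @param massRange Peptide neutral-mass bounds, Da.
#' @param carbamidomethyl Apply fixed +57.02146 on Cys.
#' @param maxOxidation Maximum simultaneous Met oxidations enumerated.
#' @return A peptide index: `data.frame(peptide, protein, mass, modPos,
#'   modMass, sites)` sorted by mass, where `modPos`/`modMass` are
#'   `;`-separated position:mass encodings and `sites` the 1-based
#'   sequon asparagine positions within the peptide.
#' @examples
#' idx <- digestProteome(c(P1 = "MKNGSAAARLK"))
#' idx$peptide
#' @export
digestProteome <- function(fasta, maxMissedCleavages = 3L,
                           lengthRange = c(6L, 40L),
                           massRange = c(600, 4500),
                           carbamidomethyl = TRUE, maxOxidation = 2L) {
  if (is.character(fasta) && length(fasta) == 1L && file.exists(fasta)) {
    aa <- Biostrings::readAAStringSet(fasta)
    prots <- stats::setNames(as.character(aa), names(aa))
  } else prots <- fasta
  if (!length(prots)) stop("empty protein input", call. = FALSE)
  names(prots) <- sub("\\s.*", "", names(prots))
  rows <- list()
  for (pid in names(prots)) {
    seqs <- .trypticPeptides(prots[[pid]], maxMissedCleavages)
    for (pep in seqs) {
      n <- nchar(pep)
      if (n < lengthRange[1] || n > lengthRange[2]) next
      sites <- .sequonPositions(pep)
      if (!length(sites)) next
      for (v in .modVariants(pep, carbamidomethyl, maxOxidation)) {
        m <- peptideMass(pep, v$mass)
        if (m < massRange[1] || m > massRange[2]) next
        rows[[length(rows) + 1L]] <- data.frame(
          peptide = pep, protein = pid, mass = m,
          modPos = paste(v$pos, collapse = ";"),
          modMass = paste(format(v$mass, trim = TRUE, digits = 10),
                          collapse = ";"),
          sites = paste(sites, collapse = ";"),
          stringsAsFactors = FALSE)
      }
    }
  }
  idx <- if (length(rows)) do.call(rbind, rows) else
    data.frame(peptide = character(0), protein = character(0),
               mass = numeric(0), modPos = character(0),
               modMass = character(0), sites = character(0))
  idx <- idx[!duplicated(idx[c("peptide", "modPos")]) |
               !duplicated(idx$protein), , drop = FALSE]
  idx <- idx[order(idx$mass), , drop = FALSE]
  rownames(idx) <- NULL
  idx
}

.trypticPeptides <- function(protein, maxMissed) {
  aa <- strsplit(protein, "")[[1]]
  n <- length(aa)
  cut <- which(aa %in% c("K", "R"))
  cut <- cut[cut < n & aa[pmin(cut + 1L, n)] != "P" | cut == n]
  bounds <- c(0L, cut, if (!n %in% cut) n)
  bounds <- sort(unique(bounds))
  out <- character(0)
  nb <- length(bounds)
  for (i in seq_len(nb - 1L)) {
    for (j in (i + 1L):min(nb, i + 1L + maxMissed)) {
      out <- c(out, substr(protein, bounds[i] + 1L, bounds[j]))
    }
  }
  unique(out)
}

.sequonPositions <- function(pep) {
  aa <- strsplit(pep, "")[[1]]
  n <- length(aa)
  which(vapply(seq_len(n), function(i)
    aa[i] == "N" && i + 2L <= n && aa[i + 1L] != "P" &&
      aa[i + 2L] %in% c("S", "T", "C"), logical(1)))
}

.modVariants <- function(pep, carbamidomethyl, maxOxidation) {
  aa <- strsplit(pep, "")[[1]]
  fixedPos <- if (carbamidomethyl) which(aa == "C") else integer(0)
  fixedMass <- rep(.MOD_MASS[["carbamidomethyl"]], length(fixedPos))
  mPos <- which(aa == "M")
  variants <- list(list(pos = fixedPos, mass = fixedMass))
  if (length(mPos) && maxOxidation > 0L) {
    for (k in seq_len(min(maxOxidation, length(mPos)))) {
      combos <- utils::combn(mPos, k, simplify = FALSE)
      if (length(combos) > 10L) combos <- combos[seq_len(10L)]
      for (cb in combos)
        variants[[length(variants) + 1L]] <- list(
          pos = c(fixedPos, cb),
          mass = c(fixedMass, rep(.MOD_MASS[["oxidation"]], k)))
    }
  }
  variants
}

# Parse ";"-separated encodings back into numeric vectors.
.splitNum <- function(x) {
  if (is.na(x) || !nzchar(x)) return(numeric(0))
  as.numeric(strsplit(x, ";")[[1]])
}

#' Query a peptide index by neutral mass
#'
#' @param index Peptide index from [digestProteome()] (mass-sorted).
#' @param mass Neutral mass, Da.
#' @param tolPpm Tolerance, ppm.
#' @return Subset of the index rows within tolerance.
#' @export
queryPeptideIndex <- function(index, mass, tolPpm = 10) {
  dm <- mass * tolPpm * 1e-6
  lo <- findInterval(mass - dm, index$mass)
  hi <- findInterval(mass + dm, index$mass)
  if (hi > lo) index[(lo + 1L):hi, , drop = FALSE] else index[0, ]
}

#' Reverse-sequence decoy peptide index
#'
#' Reverses each peptide while keeping the C-terminal residue in place
#' (preserving the tryptic terminus), remapping modification positions
#' and sequon annotations accordingly.
#'
#' @param index Peptide index.
#' @return Decoy index of the same shape, proteins prefixed `rev_`.
#' @export
decoyPeptideIndex <- function(index) {
  if (!nrow(index)) return(index)
  rev1 <- function(p) {
    a <- strsplit(p, "")[[1]]
    n <- length(a)
    paste(c(rev(a[-n]), a[n]), collapse = "")
  }
  out <- index
  out$peptide <- vapply(index$peptide, rev1, character(1))
  out$protein <- paste0("rev_", index$protein)
  remap <- function(posStr, n) {
    pos <- .splitNum(posStr)
    paste(ifelse(pos == n, pos, n - pos), collapse = ";")
  }
  n <- nchar(index$peptide)
  out$modPos <- mapply(remap, index$modPos, n)
  out$sites <- mapply(remap, index$sites, n)
  out[order(out$mass), , drop = FALSE]
}

#' Import externally produced peptide-spectrum matches
#'
#' Reads a TSV of initial PSMs (an external engine's output), keeps
#' matches with q below the threshold, and drops peptides lacking an
#' N-glycosylation sequon with a warning.
#'
#' @param path TSV with columns `scanId`, `peptide`, `mods`, `score`,
#'   `q` (mods as `pos:mass;pos:mass`, may be empty).
#' @param qThreshold Maximum q value retained.
#' @return `data.frame(scanId, peptide, modPos, modMass, score, q)`.
#' @export
loadInitialPsms <- function(path, qThreshold = 0.01) {
  empty <- data.frame(scanId = character(0), peptide = character(0),
                      modPos = character(0), modMass = character(0),
                      score = numeric(0), q = numeric(0))
  if (!length(readLines(path, n = 1L))) return(empty)
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("scanId", "peptide", "mods", "score", "q")
  miss <- setdiff(need, names(tab))
  if (length(miss))
    stop("PSM table lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (!nrow(tab)) return(empty)
  parsed <- lapply(seq_len(nrow(tab)), function(i) {
    tryCatch({
      mp <- character(0); mm <- character(0)
      if (nzchar(tab$mods[i]) && !is.na(tab$mods[i])) {
        parts <- strsplit(tab$mods[i], ";")[[1]]
        kv <- strsplit(parts, ":")
        pos <- suppressWarnings(
          vapply(kv, function(x) as.numeric(x[1]), numeric(1)))
        mass <- suppressWarnings(
          vapply(kv, function(x) as.numeric(x[2]), numeric(1)))
        if (anyNA(pos) || anyNA(mass) ||
            any(lengths(kv) != 2L)) stop("bad mod string")
        mp <- paste(pos, collapse = ";")
        mm <- paste(format(mass, trim = TRUE, digits = 10),
                    collapse = ";")
      } else { mp <- ""; mm <- "" }
      data.frame(scanId = as.character(tab$scanId[i]),
                 peptide = tab$peptide[i], modPos = mp, modMass = mm,
                 score = tab$score[i], q = tab$q[i],
                 stringsAsFactors = FALSE)
    }, error = function(e) {
      warning("row ", i, " skipped: ", conditionMessage(e),
              call. = FALSE)
      NULL
    })
  })
  psms <- do.call(rbind, parsed[!vapply(parsed, is.null, logical(1))])
  psms <- psms[psms$q < qThreshold, , drop = FALSE]
  hasSequon <- vapply(psms$peptide,
                      function(p) length(.sequonPositions(p)) > 0,
                      logical(1))
  if (any(!hasSequon))
    warning(sum(!hasSequon), " PSM(s) without a sequon dropped")
  psms <- psms[hasSequon, , drop = FALSE]
  rownames(psms) <- NULL
  psms
}

#' Minimal built-in search of deglycosylated spectra
#'
#' Scores each in-silico deglycosylated spectrum against the sequon
#' peptide index by shared-peak count and intensity over theoretical b/y
#' ions (including b/y+HexNAc variants at the sequon asparagine), with
#' reversed-sequence decoys providing target-decoy q values.  This is a
#' self-contained stand-in for an external proteomic search engine.
#'
#' @param spectra Deglycosylated spectra ([deglycosylateRun()] output);
#'   precursor = peptide+HexNAc by construction.
#' @param index Peptide index from [digestProteome()].
#' @param precTolPpm Precursor (peptide-mass) tolerance, ppm.
#' @param fragTolPpm Fragment tolerance, ppm.
#' @param minMatched Minimum matched fragment ions for a reportable
#'   PSM (guards against chance matches in sparse spectra).
#' @return `data.frame(scanId, sourceScan, peptide, protein, modPos,
#'   modMass, pepMass, rt, score, q)` with the best PSM per source scan.
#' @export
builtinSearch <- function(spectra, index, precTolPpm = 10,
                          fragTolPpm = 20, minMatched = 4L) {
  if (!nrow(index)) stop("empty peptide index", call. = FALSE)
  decoy <- decoyPeptideIndex(index)
  hexnac <- monosaccharideMasses()[["HexNAc"]]
  scoreOne <- function(s, idx) {
    P <- precursorMass(s) - hexnac
    cand <- queryPeptideIndex(idx, P, precTolPpm)
    if (!nrow(cand)) return(NULL)
    base <- if (length(s@intensity)) max(s@intensity) else 1
    best <- NULL
    for (i in seq_len(nrow(cand))) {
      frag <- theoreticalPeptideFragments(
        cand$peptide[i], .splitNum(cand$modPos[i]),
        .splitNum(cand$modMass[i]),
        hexnacSite = .splitNum(cand$sites[i])[1])
      hits <- .matchFragments(s, frag$mz, fragTolPpm)
      sc <- sum(hits$matched) / 2 + sum(s@intensity[hits$peak]) / base
      if (is.null(best) || sc > best$score)
        best <- list(row = cand[i, ], score = sc,
                     nMatched = sum(hits$matched))
    }
    best
  }
  rows <- list()
  for (s in spectra) {
    tHit <- scoreOne(s, index)
    dHit <- scoreOne(s, decoy)
    hit <- NULL; isDecoy <- FALSE
    if (!is.null(tHit) && (is.null(dHit) || tHit$score >= dHit$score))
      hit <- tHit
    else if (!is.null(dHit)) { hit <- dHit; isDecoy <- TRUE }
    if (is.null(hit) || hit$nMatched < minMatched) next
    rows[[length(rows) + 1L]] <- data.frame(
      scanId = s@scanId,
      sourceScan = sub("\\|pep=.*$", "", s@scanId),
      peptide = hit$row$peptide, protein = hit$row$protein,
      modPos = hit$row$modPos, modMass = hit$row$modMass,
      pepMass = hit$row$mass, rt = s@rt,
      score = hit$score, decoy = isDecoy, stringsAsFactors = FALSE)
  }
  if (!length(rows))
    return(data.frame(scanId = character(0), sourceScan = character(0),
                      peptide = character(0), protein = character(0),
                      modPos = character(0), modMass = character(0),
                      pepMass = numeric(0), rt = numeric(0),
                      score = numeric(0), q = numeric(0)))
  psms <- do.call(rbind, rows)
  # target-decoy q values over the pooled score distribution
  o <- order(-psms$score)
  psms <- psms[o, , drop = FALSE]
  nd <- cumsum(psms$decoy)
  nt <- cumsum(!psms$decoy)
  fdr <- ifelse(nt > 0, nd / nt, 1)
  psms$q <- rev(cummin(rev(fdr)))
  psms <- psms[!psms$decoy, , drop = FALSE]
  # best PSM per source scan
  psms <- psms[order(psms$q, -psms$score), , drop = FALSE]
  psms <- psms[!duplicated(psms$sourceScan), , drop = FALSE]
  psms$decoy <- NULL
  rownames(psms) <- NULL
  psms
}

# Vectorised fragment matching: which theoretical m/z values have a peak
# within tolPpm; returns matched flags and the matched peak index.
.matchFragments <- function(s, theo, tolPpm) {
  if (!length(s@mz) || !length(theo))
    return(list(matched = logical(length(theo)),
                peak = integer(0)))
  idx <- findInterval(theo, s@mz)
  lo <- pmax(idx, 1L)
  hi <- pmin(idx + 1L, length(s@mz))
  dLo <- abs(s@mz[lo] - theo)
  dHi <- abs(s@mz[hi] - theo)
  best <- ifelse(dLo <= dHi, lo, hi)
  dist <- pmin(dLo, dHi)
  matched <- dist <= theo * tolPpm * 1e-6
  list(matched = matched, peak = unique(best[matched]),
       peakPer = ifelse(matched, best, NA_integer_))
}
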