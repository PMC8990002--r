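# End-to-end orchestration: screening, in-silico deglycosylation,
# backbone search, spectrum expansion, precursor correction, glycan
# annotation, glycan FDR, mass profiling and quantification.

#' Pipeline configuration
#'
#' @param precursorTolPpm Precursor mass tolerance, ppm.
#' @param fragmentTolPpm Fragment mass tolerance, ppm.
#' @param alpha Intensity exponent of the expansion and glycan scores.
#' @param minOxonium Oxonium screening threshold (distinct ions).
#' @param minCoreIons Core Y ions required per backbone candidate.
#' @param maxCoreCandidates Backbone candidates retained per spectrum.
#' @param qThreshold q-value cutoff for initial PSMs.
#' @param fdrThreshold FDR cutoff for expansion and glycan acceptance.
#' @param rtWindow Expansion retention-time half-window, seconds.
#' @param moietyRange Stepping moiety-mass interval, Da.
#' @param seed Global seed, fanned out per stage.
#' @return Configuration list of class `runConfig`.
#' @export
runConfig <- function(precursorTolPpm = 5, fragmentTolPpm = 20,
                      alpha = 0.3, minOxonium = 3L, minCoreIons = 3L,
                      maxCoreCandidates = 5L, qThreshold = 0.01,
                      fdrThreshold = 0.01, rtWindow = 1800,
                      moietyRange = c(1, 300), seed = 1L) {
  cfg <- as.list(environment())
  stopifnot(all(unlist(cfg[c("precursorTolPpm", "fragmentTolPpm",
                             "alpha", "minOxonium", "minCoreIons",
                             "maxCoreCandidates", "fdrThreshold",
                             "rtWindow")]) > 0),
            qThreshold >= 0)
  structure(cfg, class = "runConfig")
}

#' @rdname runConfig
#' @param path YAML file with (a subset of) the configuration fields.
#' @export
readRunConfig <- function(path) {
  vals <- yaml::read_yaml(path)
  cfg <- do.call(runConfig, vals[intersect(names(vals),
                                           names(formals(runConfig)))])
  cfg
}

# Stable per-stage seed fan-out from the global seed.
.stageSeed <- function(seed, stage) {
  (as.integer(seed) * 1009L + sum(utf8ToInt(stage))) %%
    .Machine$integer.max
}

#' Run the full identification and quantification pipeline
#'
#' Stages, in order: oxonium screening and in-silico deglycosylation;
#' backbone search of the deglycosylated spectra (built-in scorer, or
#' externally supplied PSMs); re-scoring of stage-one PSMs with the
#' pattern-aware score; spectrum expansion per backbone; precursor
#' monoisotope correction; glycan-mass harmonisation; glycan annotation
#' by database matching then monosaccharide stepping; glycan-level FDR;
#' mass profiling; and MS1 elution-profile quantification with
#' site-level normalisation.
#'
#' @param ms2 List of [Ms2Spectrum-class].
#' @param index Peptide index ([digestProteome()]).
#' @param glycanDb Glycan database ([readGlycanDb()]).
#' @param cfg A [runConfig()].
#' @param ms1 Optional [Ms1Map-class] (enables precursor correction and
#'   quantification).
#' @param psms Optional externally produced stage-one PSM table (as
#'   from [loadInitialPsms()], plus `pepMass`, `sourceScan`, `rt`);
#'   when `NULL` the built-in scorer is used.
#' @param outDir Optional directory for TSV outputs (`psms.tsv`,
#'   `expansion_psms.tsv`, `gpsms.tsv`, `glycan_profile.tsv`,
#'   `quant.tsv`, `site_distribution.tsv`).
#' @return Result bundle: `psms`, `expansion`, `gpsms`, `profiles`,
#'   `quant`, `siteDistribution`, `summary` (per-stage counts) and
#'   `config`.
#' @export
runPipeline <- function(ms2, index, glycanDb, cfg = runConfig(),
                        ms1 = NULL, psms = NULL, outDir = NULL) {
  stopifnot(inherits(cfg, "runConfig"))
  specByScan <- stats::setNames(ms2, vapply(ms2, scanId, character(1)))
  ## stage 1: screening + deglycosylation + backbone search
  deg <- deglycosylateRun(ms2, tolPpm = cfg$fragmentTolPpm,
                          minOxonium = cfg$minOxonium,
                          minCoreIons = cfg$minCoreIons,
                          maxCandidates = cfg$maxCoreCandidates)
  nScreened <- length(unique(deg$candidates$scanId))
  if (is.null(psms)) {
    psms <- builtinSearch(deg$spectra, index,
                          precTolPpm = cfg$precursorTolPpm,
                          fragTolPpm = cfg$fragmentTolPpm)
    psms <- psms[psms$q < cfg$qThreshold, , drop = FALSE]
  }
  ## stage 2: fragmentation patterns + expansion
  freqIndex <- buildFrequencyIndex(index, cfg$fragmentTolPpm)
  assigned <- unique(psms$sourceScan)
  backboneKey <- paste0(psms$peptide, "/", psms$modPos)
  expansion <- .emptyExpansion()
  patterns <- list()
  for (key in unique(backboneKey)) {
    sel <- psms[backboneKey == key, , drop = FALSE]
    pats <- lapply(sel$sourceScan, function(sc) {
      s <- specByScan[[sc]]
      if (is.null(s)) return(NULL)
      extractPattern(s, sel$peptide[1], .splitNum(sel$modPos[1]),
                     .splitNum(sel$modMass[1]), cfg$fragmentTolPpm)
    })
    pats <- pats[!vapply(pats, is.null, logical(1))]
    if (!length(pats)) next
    avg <- averagePattern(pats)
    patterns[[key]] <- avg
    pepRow <- list(peptide = sel$peptide[1], modPos = sel$modPos[1],
                   modMass = sel$modMass[1], mass = sel$pepMass[1])
    unassigned <- specByScan[setdiff(names(specByScan), assigned)]
    if (!length(unassigned)) next
    ex <- expandPeptide(pepRow, avg, unname(unassigned), freqIndex,
                        rtWindow = cfg$rtWindow, alpha = cfg$alpha,
                        tolPpm = cfg$fragmentTolPpm,
                        fdrThreshold = cfg$fdrThreshold,
                        seed = .stageSeed(cfg$seed, "expansion"))
    expansion <- rbind(expansion, ex)
  }
  accepted <- expansion[expansion$accepted, , drop = FALSE]
  # one backbone per expanded spectrum: best e-value wins
  if (nrow(accepted)) {
    accepted <- accepted[order(accepted$evalue), , drop = FALSE]
    accepted <- accepted[!duplicated(accepted$scanId), , drop = FALSE]
  }
  ## stage 3: precursor correction + glycan annotation
  gRows <- list()
  addG <- function(scan, peptide, modPos, modMass, pepMass, stage) {
    s <- specByScan[[scan]]
    if (is.null(s)) return()
    pepEl <- peptideElements(peptide, .splitNum(modMass))
    corr <- correctPrecursor(s, pepMass, pepEl, ms1,
                             tolPpm = cfg$fragmentTolPpm)
    gm <- corr$mass - pepMass
    if (gm <= 0) return()
    gRows[[length(gRows) + 1L]] <<- data.frame(
      scanId = scan, peptide = peptide, modPos = modPos,
      modMass = modMass, pepMass = pepMass, stage = stage,
      charge = s@precursorCharge, rt = s@rt,
      precursorMass = corr$mass, isotopeOffset = corr$offset,
      glycanMass = gm, stringsAsFactors = FALSE)
  }
  for (i in seq_len(nrow(psms)))
    addG(psms$sourceScan[i], psms$peptide[i], psms$modPos[i],
         psms$modMass[i], psms$pepMass[i], "deglyco")
  for (i in seq_len(nrow(accepted)))
    addG(accepted$scanId[i], accepted$peptide[i], accepted$modPos[i],
         accepted$modMass[i], accepted$pepMass[i], "expansion")
  gpsms <- if (length(gRows)) do.call(rbind, gRows) else NULL
  if (!is.null(gpsms)) {
    gpsms$glycanMass <- harmonizeGlycanMasses(gpsms$glycanMass)
    ann <- lapply(seq_len(nrow(gpsms)), function(i) {
      s <- specByScan[[gpsms$scanId[i]]]
      tolDa <- max(0.01, gpsms$precursorMass[i] *
                     cfg$precursorTolPpm * 1e-6)
      hit <- annotateFromDb(s, gpsms$pepMass[i], gpsms$glycanMass[i],
                            glycanDb, tolDa, cfg$alpha,
                            cfg$fragmentTolPpm)
      if (is.null(hit))
        hit <- monosaccharideStepping(s, gpsms$pepMass[i],
                                      gpsms$glycanMass[i], glycanDb,
                                      cfg$fragmentTolPpm,
                                      cfg$moietyRange)
      hit
    })
    gpsms$composition <- vapply(ann, function(a)
      if (is.null(a)) NA_character_ else glycanLabel(a$composition),
      character(1))
    gpsms$route <- vapply(ann, function(a)
      if (is.null(a)) "unannotated" else a$route, character(1))
    gpsms$moietyMass <- vapply(ann, function(a)
      if (is.null(a) || is.null(a$moietyMass)) 0 else a$moietyMass,
      numeric(1))
    gpsms$glycanScore <- vapply(seq_along(ann), function(i) {
      a <- ann[[i]]
      if (is.null(a)) return(0)
      if (!is.null(a$score)) return(a$score)
      s <- specByScan[[gpsms$scanId[i]]]
      frag <- theoreticalGlycanFragments(
        list(composition = glycanComposition(
          glycanCounts(a$composition)), topology = ""),
        gpsms$pepMass[i], maxCharge = s@precursorCharge)
      scoreGlycan(s, frag, NULL, cfg$alpha, cfg$fragmentTolPpm)$score
    }, numeric(1))
    gpsms <- glycanFdr(gpsms, specByScan, glycanDb,
                       seed = .stageSeed(cfg$seed, "glycan-fdr"),
                       alpha = cfg$alpha, tolPpm = cfg$fragmentTolPpm,
                       fdrThreshold = cfg$fdrThreshold)
  } else {
    gpsms <- data.frame()
  }
  profiles <- buildMassProfiles(
    if (nrow(gpsms)) gpsms$glycanMass else numeric(0))
  ## stage 4: quantification
  quant <- NULL; siteDist <- NULL
  if (!is.null(ms1) && nrow(gpsms)) {
    ok <- !is.na(gpsms$composition)
    gq <- gpsms[ok, , drop = FALSE]
    if (nrow(gq)) {
      key <- paste(gq$peptide, gq$modPos, gq$composition)
      qRows <- list()
      for (k in unique(key)) {
        sel <- gq[key == k, , drop = FALSE]
        pepEl <- peptideElements(sel$peptide[1],
                                 .splitNum(sel$modMass[1]))
        prof <- quantifyGlycopeptide(
          pepEl, stats::median(sel$glycanMass),
          charges = unique(sel$charge),
          rt = stats::median(sel$rt), ms1 = ms1,
          tolPpm = cfg$fragmentTolPpm)
        site <- .siteForPeptide(index, sel$peptide[1])
        qRows[[length(qRows) + 1L]] <- data.frame(
          peptide = sel$peptide[1], modPos = sel$modPos[1],
          protein = site$protein, site = site$site,
          glycan = sel$composition[1], nPsms = nrow(sel),
          area = prof$area, flag = prof$flag,
          stringsAsFactors = FALSE)
      }
      quant <- do.call(rbind, qRows)
      siteDist <- siteDistribution(quant)
    }
  }
  summary <- data.frame(
    stage = c("ms2", "screened", "deglyco-psms", "expansion-psms",
              "gpsms", "annotated", "quantified"),
    count = c(length(ms2), nScreened, nrow(psms), nrow(accepted),
              nrow(gpsms),
              if (nrow(gpsms)) sum(!is.na(gpsms$composition)) else 0L,
              if (is.null(quant)) 0L else nrow(quant)))
  res <- list(psms = psms, expansion = expansion,
              expansionAccepted = accepted, gpsms = gpsms,
              patterns = patterns, profiles = profiles, quant = quant,
              siteDistribution = siteDist, summary = summary,
              config = cfg)
  if (!is.null(outDir)) .writeBundle(res, outDir)
  res
}

# Protein and site (residue index) for a peptide via the digest index.
.siteForPeptide <- function(index, peptide) {
  row <- index[index$peptide == peptide, , drop = FALSE]
  if (!nrow(row))
    return(list(protein = NA_character_, site = NA_integer_))
  list(protein = row$protein[1],
       site = .splitNum(row$sites[1])[1])
}

.writeBundle <- function(res, outDir) {
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  hash <- sum(utf8ToInt(paste(deparse(res$config), collapse = ""))) %%
    1000000L
  w <- function(obj, name) {
    if (is.null(obj) || !nrow(obj)) return()
    path <- file.path(outDir, name)
    con <- file(path, "w")
    writeLines(sprintf("# config-hash: %06d", hash), con)
    utils::write.table(obj, con, sep = "\t", row.names = FALSE,
                       quote = FALSE)
    close(con)
  }
  w(res$psms, "psms.tsv")
  w(res$expansion, "expansion_psms.tsv")
  w(res$gpsms, "gpsms.tsv")
  w(res$profiles$precise, "glycan_profile.tsv")
  w(res$quant, "quant.tsv")
  w(res$siteDistribution, "site_distribution.tsv")
  invisible(outDir)
}
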