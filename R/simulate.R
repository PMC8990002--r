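# Synthetic LC-MS/MS glycoproteomics runs with ground truth: sceHCD-like
# glycopeptide MS2 spectra (oxonium ions, B ions, the core Y ladder,
# stepped Y series, b/y ions with losses and glycan-dependent
# suppression) over Gaussian MS1 elution profiles.

#' Simulation configuration
#'
#' Defaults describe a small but structurally complete glycoproteomics
#' run: tryptic sequon peptides carrying mixed neutral and sialylated
#' glycans, scan repeats across a Gaussian elution peak, uniform noise
#' peaks, and regular MS1 sampling.
#'
#' @param seed Mandatory integer seed; the whole run is a deterministic
#'   function of the configuration.
#' @param nProteins Synthetic proteins generated when no FASTA given.
#' @param nPeptides Glycopeptide backbones drawn from the digest.
#' @param glycansPerSite Glycoforms simulated per backbone.
#' @param scansPerGlycoform MS2 scans per glycoform across its peak.
#' @param moietyFraction Fraction of glycoforms carrying a modified
#'   glycan (a moiety from `moietyMasses` on top of a database glycan).
#' @param moietyMasses Moiety masses sampled for modified glycans, Da
#'   (defaults: ammonium adduct 17.0265, phosphate 79.9663).
#' @param suppressionFactor Fraction of b/y intensity removed for
#'   sialylated glycoforms (their peptide fragments are weaker in HCD).
#' @param noisePeaks Uniform random noise peaks per MS2 spectrum.
#' @param ms1Interval MS1 sampling interval, seconds.
#' @param peakWidth Chromatographic peak sigma, seconds.
#' @param gradientLength Run length, seconds.
#' @param charges Precursor charges sampled per glycoform.
#' @param abundances Optional fixed glycoform abundance ratios recycled
#'   per backbone (e.g. `c(5, 3, 2)`); default log-normal draws.
#' @return Configuration list of class `simConfig`.
#' @export
simConfig <- function(seed, nProteins = 4L, nPeptides = 8L,
                      glycansPerSite = 3L, scansPerGlycoform = 3L,
                      moietyFraction = 0,
                      moietyMasses = c(17.0265, 79.9663),
                      suppressionFactor = 0, noisePeaks = 10L,
                      ms1Interval = 2, peakWidth = 10,
                      gradientLength = 1200, charges = 2:3,
                      abundances = NULL) {
  if (missing(seed)) stop("seed is mandatory", call. = FALSE)
  stopifnot(moietyFraction >= 0, moietyFraction <= 1,
            suppressionFactor >= 0, suppressionFactor <= 1)
  structure(as.list(environment()), class = "simConfig")
}

# Default glycan set: truncated, oligo-mannose and complex/hybrid
# compositions incl. sialylated species for suppression experiments.
defaultSimGlycans <- function() {
  c("Hex(3)HexNAc(2)", "Hex(4)HexNAc(2)", "Hex(5)HexNAc(2)",
    "Hex(6)HexNAc(2)", "Hex(7)HexNAc(2)", "Hex(8)HexNAc(2)",
    "Hex(9)HexNAc(2)",
    "Hex(3)HexNAc(3)", "Hex(3)HexNAc(4)", "Hex(4)HexNAc(3)",
    "Hex(5)HexNAc(2)Fuc(1)", "Hex(4)HexNAc(4)", "Hex(5)HexNAc(4)",
    "Hex(5)HexNAc(4)Fuc(1)", "Hex(5)HexNAc(4)NeuAc(1)",
    "Hex(5)HexNAc(4)NeuAc(2)", "Hex(5)HexNAc(4)NeuAc(1)Fuc(1)",
    "Hex(6)HexNAc(5)NeuAc(1)", "Hex(5)HexNAc(5)NeuAc(1)",
    "Hex(6)HexNAc(3)")
}

# Random sequon-bearing synthetic proteins: concatenated tryptic
# peptides, each with one N-X-S/T motif and a K/R terminus.
.simProteins <- function(n, perProtein = 4L) {
  alphabet <- c("A", "G", "S", "T", "V", "L", "I", "F", "Y", "D", "E",
                "Q", "H", "W")
  mkPep <- function() {
    len <- sample(7:14, 1)
    aa <- sample(alphabet, len, replace = TRUE)
    pos <- sample(2:(len - 3), 1)
    aa[pos] <- "N"
    aa[pos + 1L] <- sample(setdiff(alphabet, "P"), 1)
    aa[pos + 2L] <- sample(c("S", "T"), 1)
    paste(c(aa, sample(c("K", "R"), 1)), collapse = "")
  }
  prots <- vapply(seq_len(n), function(i)
    paste(vapply(seq_len(perProtein), function(j) mkPep(),
                 character(1)), collapse = ""), character(1))
  stats::setNames(prots, sprintf("SIMPROT%02d", seq_len(n)))
}

# Y-ion stepping chain of a glycan: cumulative glycan-part masses from
# the pentasaccharide core to the full glycan, remaining residues in
# registry order, the moiety last.
.steppingChain <- function(comp) {
  monos <- monosaccharideMasses()
  cnt <- glycanCounts(comp)
  core <- c(Hex = 3, HexNAc = 2)
  rem <- cnt
  rem[names(core)] <- rem[names(core)] - core
  rem <- rem[rem > 0 & !is.na(rem)]
  gaps <- rep(monos[names(rem)], times = rem)
  if (moietyMass(comp) != 0) gaps <- c(gaps, moietyMass(comp))
  coreMass <- 3 * monos[["Hex"]] + 2 * monos[["HexNAc"]]
  cumsum(c(coreMass, gaps))
}

#' Simulate a synthetic glycoproteomics run
#'
#' Digests (or generates) proteins, attaches glycans to sequon
#' peptides, and renders MS2 spectra (oxonium ions, B ions, the full
#' core Y ladder at charges 1-2, the stepped Y series out to the intact
#' glycopeptide, b/y ions with NH3/H2O losses at charges 1-2, uniform
#' noise) plus MS1 isotope envelopes over Gaussian elution profiles.
#' Each backbone's b/y intensity pattern is drawn once and reused
#' across its glycoforms — the conserved-pattern property that spectrum
#' expansion exploits — while sialylated glycoforms lose
#' `suppressionFactor` of their b/y intensity.
#'
#' @param cfg A [simConfig()].
#' @param fasta Optional named character vector or FASTA path; default
#'   synthetic proteins.
#' @param glycans Optional character vector of composition strings.
#' @return List with `ms1` ([Ms1Map-class]), `ms2` (list of
#'   [Ms2Spectrum-class]), `truth` (one row per MS2 scan), `proteins`,
#'   `index` (the digest), `glycanDb` and `config`.
#' @export
simulateRun <- function(cfg, fasta = NULL, glycans = NULL) {
  stopifnot(inherits(cfg, "simConfig"))
  withRngSeed(cfg$seed, .simulateRunImpl(cfg, fasta, glycans))
}

.simulateRunImpl <- function(cfg, fasta, glycans) {
  prot <- massConstants[["proton"]]
  neutron <- massConstants[["neutron"]]
  monos <- monosaccharideMasses()
  proteins <- if (is.null(fasta)) .simProteins(cfg$nProteins) else {
    if (length(fasta) == 1L && file.exists(fasta)) {
      aa <- Biostrings::readAAStringSet(fasta)
      stats::setNames(as.character(aa), sub("\\s.*", "", names(aa)))
    } else fasta
  }
  index <- digestProteome(proteins, maxOxidation = 0L)
  if (!nrow(index))
    stop("no sequon-bearing peptides in the protein input",
         call. = FALSE)
  base <- index[!duplicated(index$peptide), , drop = FALSE]
  nPep <- min(cfg$nPeptides, nrow(base))
  pepRows <- base[sample(nrow(base), nPep), , drop = FALSE]
  if (is.null(glycans)) glycans <- defaultSimGlycans()
  glycanDb <- glycanDbFromCompositions(glycans)
  # per-backbone conserved b/y pattern and mean retention time
  backbones <- lapply(seq_len(nPep), function(i) {
    pep <- pepRows$peptide[i]
    n <- nchar(pep)
    types <- c(paste0("b", 1:(n - 1)), paste0("y", 1:(n - 1)))
    list(row = pepRows[i, ],
         pattern = stats::setNames(stats::rlnorm(length(types), 0, 0.8),
                                   types),
         rt = stats::runif(1, 150, cfg$gradientLength - 150))
  })
  glycoforms <- list()
  for (b in backbones) {
    picks <- sample(nrow(glycanDb), min(cfg$glycansPerSite,
                                        nrow(glycanDb)))
    ab <- if (!is.null(cfg$abundances))
      rep_len(cfg$abundances, length(picks)) else
        stats::rlnorm(length(picks), 0, 0.6)
    for (j in seq_along(picks)) {
      comp <- parseGlycanComposition(glycanDb$composition[picks[j]])
      moiety <- 0
      if (stats::runif(1) < cfg$moietyFraction)
        moiety <- cfg$moietyMasses[
          sample.int(length(cfg$moietyMasses), 1)]
      if (moiety != 0)
        comp <- glycanComposition(glycanCounts(comp),
                                  moietyMass = moiety)
      glycoforms[[length(glycoforms) + 1L]] <- list(
        backbone = b, comp = comp,
        glycanMass = glycanMass(comp),
        z = cfg$charges[sample.int(length(cfg$charges), 1)],
        abundance = ab[j],
        rt = b$rt + stats::rnorm(1, 0, 2))
    }
  }
  # MS1 frames
  frameRt <- seq(0, cfg$gradientLength, by = cfg$ms1Interval)
  frameMz <- vector("list", length(frameRt))
  frameInt <- vector("list", length(frameRt))
  nIso <- 4L
  for (g in glycoforms) {
    pepEl <- peptideElements(g$backbone$row$peptide,
                             .splitNum(g$backbone$row$modMass))
    env <- isotopePattern(ecSum(pepEl,
                                pseudoGlycanElements(g$glycanMass)),
                          nPeaks = nIso)$abundance
    mono <- (g$backbone$row$mass + g$glycanMass + g$z * prot) / g$z
    sel <- which(abs(frameRt - g$rt) < 4 * cfg$peakWidth)
    for (fi in sel) {
      h <- g$abundance * 1e6 *
        exp(-(frameRt[fi] - g$rt)^2 / (2 * cfg$peakWidth^2))
      if (h <= 1) next
      frameMz[[fi]] <- c(frameMz[[fi]], mono + (0:(nIso - 1L)) *
                           neutron / g$z)
      frameInt[[fi]] <- c(frameInt[[fi]], h * env)
    }
  }
  frames <- lapply(seq_along(frameRt), function(fi) {
    mz <- frameMz[[fi]]; it <- frameInt[[fi]]
    if (is.null(mz)) return(list(mz = numeric(0),
                                 intensity = numeric(0)))
    o <- order(mz)
    list(mz = mz[o], intensity = it[o])
  })
  ms1 <- ms1Map(frameRt, frames)
  # MS2 scans
  ms2 <- list(); truthRows <- list()
  scanNo <- 0L
  for (g in glycoforms) {
    pepMass <- g$backbone$row$mass
    pep <- g$backbone$row$peptide
    sial <- any(c("NeuAc", "NeuGc") %in%
                  names(glycanCounts(g$comp)[glycanCounts(g$comp) > 0]))
    byScale <- if (sial) 1 - cfg$suppressionFactor else 1
    chain <- .steppingChain(g$comp)
    scanRts <- g$rt + seq(-0.6, 0.6,
                          length.out = cfg$scansPerGlycoform) *
      cfg$peakWidth
    for (rt in scanRts) {
      scanNo <- scanNo + 1L
      id <- sprintf("sim%05d", scanNo)
      mz <- numeric(0); it <- numeric(0)
      add <- function(m, i) { mz <<- c(mz, m); it <<- c(it, i) }
      # oxonium ions and the HexNAc/Hex B series
      add(c(126.0550, 138.0549, 168.0655, 186.0761, 204.0867,
            163.0601, 366.1395),
          c(0.15, 0.25, 0.2, 0.3, 1.0, 0.35, 0.6))
      if (sial) add(c(274.0921, 292.1027), c(0.5, 0.45))
      # core Y ladder (charge 1 and 2), Y1 prominent
      off <- coreYOffsets()
      yInt <- c(Y0 = 0.5, Y1 = 0.95, Y2 = 0.7, Y3 = 0.55, Y4 = 0.45,
                Y5 = 0.4)
      for (k in seq_along(off)) {
        add((pepMass + off[k] + prot) / 1, yInt[k])
        if (g$z >= 2) add((pepMass + off[k] + 2 * prot) / 2,
                          yInt[k] * 0.3)
      }
      # stepped Y series beyond the core up to the intact glycopeptide
      beyond <- chain[chain > max(off) + 1e-6]
      for (ym in beyond) add((pepMass + ym + prot) / 1, 0.3)
      add((pepMass + g$glycanMass + g$z * prot) / g$z, 0.35)
      # conserved-pattern b/y ions with losses, suppressed if sialylated
      rmass <- residueMasses(pep, .splitNum(g$backbone$row$modPos),
                             .splitNum(g$backbone$row$modMass))
      n <- length(rmass)
      bN <- cumsum(rmass)[-n]
      yN <- rev(cumsum(rev(rmass)))[-1] + massConstants[["water"]]
      pat <- g$backbone$pattern
      for (i in seq_len(n - 1L)) {
        bI <- pat[[paste0("b", i)]] * 0.25 * byScale
        yI <- pat[[paste0("y", i)]] * 0.25 * byScale
        if (bI > 0.001) {
          add(bN[i] + prot, bI)
          add(bN[i] - massConstants[["ammonia"]] + prot, bI * 0.2)
        }
        if (yI > 0.001) {
          add(rev(yN)[i] + prot, yI)
          add(rev(yN)[i] - massConstants[["water"]] + prot, yI * 0.2)
        }
      }
      # uniform noise
      if (cfg$noisePeaks > 0) {
        maxMz <- (pepMass + g$glycanMass + prot)
        add(stats::runif(cfg$noisePeaks, 150, maxMz),
            stats::runif(cfg$noisePeaks, 0.005, 0.04))
      }
      scale <- g$abundance * 1e5
      ms2[[scanNo]] <- ms2Spectrum(
        id, (pepMass + g$glycanMass + g$z * prot) / g$z, g$z, rt,
        mz, it * scale)
      truthRows[[scanNo]] <- data.frame(
        scanId = id, peptide = pep,
        modPos = g$backbone$row$modPos,
        modMass = g$backbone$row$modMass,
        protein = g$backbone$row$protein,
        site = .splitNum(g$backbone$row$sites)[1],
        pepMass = pepMass, glycan = glycanLabel(g$comp),
        moietyMass = moietyMass(g$comp),
        glycanMass = g$glycanMass, abundance = g$abundance,
        charge = g$z, rt = rt, suppressed = FALSE,
        stringsAsFactors = FALSE)
    }
  }
  list(ms1 = ms1, ms2 = ms2, truth = do.call(rbind, truthRows),
       proteins = proteins, index = index, glycanDb = glycanDb,
       config = cfg)
}

#' Apply a targeted corruption to a simulated run
#'
#' Stresses individual pipeline stages while preserving ground truth:
#' `drop_by` removes the peptide b/y fragment peaks from a fraction of
#' spectra (emulating glycopeptide spectra whose backbone fragments are
#' absent, as for strongly sialylated species);
#' `shift_precursor_isotope` moves the reported precursor m/z to the
#' +1 isotopologue; `add_moiety` is provided by the generator itself
#' via `moietyFraction` (corrupting after the fact would desynchronise
#' the Y ladder) and is rejected here.
#'
#' @param run A [simulateRun()] result.
#' @param mode `"drop_by"` or `"shift_precursor_isotope"`.
#' @param fraction Fraction of spectra affected.
#' @param seed Selection seed.
#' @param tolPpm Matching tolerance for b/y removal.
#' @return The corrupted run; `truth` gains a `suppressed` or
#'   `isoShifted` flag.
#' @export
corruptRun <- function(run, mode = c("drop_by",
                                     "shift_precursor_isotope"),
                       fraction = 0.4, seed = 1L, tolPpm = 20) {
  mode <- match.arg(mode)
  n <- length(run$ms2)
  pick <- withRngSeed(seed + 17L, sample(n, round(fraction * n)))
  if (mode == "drop_by") {
    run$truth$suppressed <- FALSE
    for (i in pick) {
      s <- run$ms2[[i]]
      tr <- run$truth[run$truth$scanId == s@scanId, ]
      frag <- theoreticalPeptideFragments(tr$peptide,
                                          .splitNum(tr$modPos),
                                          .splitNum(tr$modMass))
      drop <- integer(0)
      for (m in frag$mz) drop <- c(drop, .peaksNear(s@mz, m, tolPpm))
      keep <- setdiff(seq_along(s@mz), unique(drop))
      run$ms2[[i]] <- ms2Spectrum(s@scanId, s@precursorMz,
                                  s@precursorCharge, s@rt,
                                  s@mz[keep], s@intensity[keep])
      run$truth$suppressed[run$truth$scanId == s@scanId] <- TRUE
    }
  } else {
    run$truth$isoShifted <- FALSE
    for (i in pick) {
      s <- run$ms2[[i]]
      run$ms2[[i]] <- ms2Spectrum(
        s@scanId,
        s@precursorMz + massConstants[["neutron"]] / s@precursorCharge,
        s@precursorCharge, s@rt, s@mz, s@intensity)
      run$truth$isoShifted[run$truth$scanId == s@scanId] <- TRUE
    }
  }
  run
}
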