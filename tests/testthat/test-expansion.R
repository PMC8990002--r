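test_that("theoretical fragments match the mass oracle", {
  frag <- theoreticalPeptideFragments("PEPTIDE", charges = 1L,
                                      losses = FALSE, nIsotopes = 0L)
  expect_equal(frag$mz[frag$type == "b2"], 227.1026, tolerance = 1e-4)
  expect_equal(frag$mz[frag$type == "y6"], 703.3145, tolerance = 1e-4)
  expect_equal(max(frag$index), nchar("PEPTIDE") - 1L)
  # b + y complementarity: b_i + y_(n-i) = peptide + 2 protons
  b3 <- frag$mz[frag$type == "b3"]
  y4 <- frag$mz[frag$type == "y4"]
  expect_equal(b3 + y4, peptideMass("PEPTIDE") + 2 * PROTON,
               tolerance = 1e-5)
  # HexNAc stub variants shift by the residue mass
  frag2 <- theoreticalPeptideFragments("NGSAAAR", hexnacSite = 1L,
                                       charges = 1L, losses = FALSE,
                                       nIsotopes = 0L)
  plain <- frag2$mz[frag2$type == "b2"]
  stub <- frag2$mz[frag2$type == "b2+HexNAc"]
  expect_equal(stub - plain, HEXNAC, tolerance = 1e-5)
})

test_that("pattern extraction normalises and sums charge states", {
  frag <- theoreticalPeptideFragments("PEPTIDE", charges = 1L,
                                      losses = FALSE, nIsotopes = 0L)
  b2 <- frag$mz[frag$type == "b2"]
  b3 <- frag$mz[frag$type == "b3"]
  s <- ms2Spectrum("s", 1000, 2L, 10, c(b2, b3), c(80, 40))
  p <- extractPattern(s, "PEPTIDE")
  expect_equal(unname(patternValues(p)[c("b2", "b3")]), c(1, 0.5))
  # same ion at 1+ and 2+ is summed before normalisation
  b2z2 <- (227.1026 - PROTON + 2 * PROTON) / 2
  s2 <- ms2Spectrum("s", 1000, 2L, 10, sort(c(b2, b2z2, b3)),
                    c(3, 1, 4)[order(c(b2, b2z2, b3))])
  p2 <- extractPattern(s2, "PEPTIDE")
  expect_equal(unname(patternValues(p2)["b2"]), 1)       # 3 + 1 = 4
  expect_equal(unname(patternValues(p2)["b3"]), 1)
  # no matches: empty pattern
  s3 <- ms2Spectrum("s", 1000, 2L, 10, c(1500.5), c(1))
  expect_length(patternValues(extractPattern(s3, "PEPTIDE")), 0L)
})

test_that("pattern averaging renormalises and counts support", {
  p1 <- new("FragmentationPattern", values = c(b2 = 1), support = 1L,
            meanRt = 100)
  p2 <- new("FragmentationPattern", values = c(b3 = 1), support = 1L,
            meanRt = 200)
  avg <- averagePattern(list(p1, p2))
  expect_equal(unname(patternValues(avg)[c("b2", "b3")]), c(1, 1))
  expect_equal(patternSupport(avg), 2L)
  expect_equal(avg@meanRt, 150)
  same <- averagePattern(list(p1, p1, p1))
  expect_equal(patternValues(same), patternValues(p1))
  expect_error(averagePattern(list()), "no patterns")
})

test_that("cosine similarity behaves at its extremes", {
  a <- new("FragmentationPattern", values = c(b2 = 1, y3 = 1),
           support = 1L, meanRt = 1)
  b <- new("FragmentationPattern", values = c(b2 = 1),
           support = 1L, meanRt = 1)
  d <- new("FragmentationPattern", values = c(y5 = 1),
           support = 1L, meanRt = 1)
  e <- new("FragmentationPattern", support = 1L, meanRt = 1)
  expect_equal(cosineSimilarity(a, a), 1)
  expect_equal(cosineSimilarity(b, d), 0)
  expect_equal(cosineSimilarity(a, b), 1 / sqrt(2), tolerance = 1e-6)
  expect_equal(cosineSimilarity(e, e), 0)
})

test_that("ion frequencies count colliding peptides, floored at one", {
  idx <- digestProteome(c(P1 = "MKNGSAAAR", P2 = "MKNGTAAAR"))
  fi <- buildFrequencyIndex(idx, tolPpm = 20)
  # an m/z far from every theoretical ion still reports 1
  expect_equal(frequencyLookup(fi, 1999.123), 1)
  # b2 of NGSAAAR is unique to it; y1 (R) is shared by both peptides
  fragS <- theoreticalPeptideFragments("NGSAAAR", charges = 1L,
                                       losses = FALSE, nIsotopes = 0L)
  y1 <- fragS$mz[fragS$type == "y1"]
  own <- paste0("NGSAAAR", "/", idx$modPos[idx$peptide == "NGSAAAR"])
  expect_gte(frequencyLookup(fi, y1, excludeId = own), 1)
})

test_that("expansion scoring follows the additive two-term form", {
  # matched b2 only, pattern identical to observation: coefficient 1,
  # frequency 1, peptide mass far away so no core term
  frag <- theoreticalPeptideFragments("PEPTIDE", charges = 1L,
                                      losses = FALSE, nIsotopes = 0L)
  b2 <- frag$mz[frag$type == "b2"]
  s <- ms2Spectrum("s", 3000, 1L, 10, b2, 100)
  avg <- new("FragmentationPattern", values = c(b2 = 1), support = 1L,
             meanRt = 10)
  pepRow <- list(peptide = "PEPTIDE", modPos = "", modMass = "",
                 mass = peptideMass("PEPTIDE"))
  sc <- scoreExpansion(s, pepRow, avg)
  expect_equal(sc$coefficient, 1, tolerance = 1e-9)
  expect_equal(sc$scorePeptide, 1, tolerance = 1e-9)
  expect_equal(sc$scoreCore, 0)
  expect_equal(sc$score, sc$scorePeptide + sc$scoreCore)
  expect_equal(sc$n, 1L)
  # two matched ions at relative intensities 1 and 0.5:
  # score = coeff * (1^0.3 + 0.5^0.3), coeff = 1
  b3 <- frag$mz[frag$type == "b3"]
  s2 <- ms2Spectrum("s", 3000, 1L, 10, c(b2, b3), c(100, 50))
  avg2 <- new("FragmentationPattern", values = c(b2 = 1, b3 = 0.5),
              support = 1L, meanRt = 10)
  sc2 <- scoreExpansion(s2, pepRow, avg2)
  expect_equal(sc2$scorePeptide, 1 + 0.5^0.3, tolerance = 1e-6)
  # core term is linear in relative intensity
  P <- peptideMass("PEPTIDE")
  sCore <- ms2Spectrum("s", 3000, 1L, 10,
                       sort(c(b2, P + PROTON, P + HEXNAC + PROTON,
                              P + 2 * HEXNAC + PROTON)),
                       c(100, 90, 30, 50)[order(c(b2, P + PROTON,
                                                  P + HEXNAC + PROTON,
                                                  P + 2 * HEXNAC +
                                                    PROTON))])
  sc3 <- scoreExpansion(sCore, pepRow, avg)
  expect_equal(sc3$m, 3L)
  expect_true(sc3$y1Matched)
  expect_equal(sc3$scoreCore, 0.9 + 0.3 + 0.5, tolerance = 1e-6)
})

test_that("the score ignores absolute intensity scale", {
  run <- smallRun(seed = 3)
  s <- run$ms2[[1]]
  tr <- run$truth[1, ]
  pepRow <- list(peptide = tr$peptide, modPos = tr$modPos,
                 modMass = tr$modMass, mass = tr$pepMass)
  avg <- extractPattern(s, tr$peptide, tolPpm = 20)
  s10 <- ms2Spectrum(scanId(s), s@precursorMz, s@precursorCharge,
                     s@rt, s@mz, s@intensity * 10)
  expect_equal(scoreExpansion(s, pepRow, avg)$score,
               scoreExpansion(s10, pepRow, avg)$score,
               tolerance = 1e-9)
})

test_that("decoy spectra shift every peak by 1-30 Th, reproducibly", {
  run <- smallRun(seed = 3)
  s <- run$ms2[[2]]
  d1 <- makeDecoySpectrum(s, seed = 9)
  d2 <- makeDecoySpectrum(s, seed = 9)
  expect_equal(d1@mz, d2@mz)
  expect_equal(sort(d1@intensity), sort(s@intensity))
  # map peaks back through their (distinct) intensities
  sel <- !duplicated(s@intensity) & !(s@intensity %in%
                                        s@intensity[duplicated(s@intensity)])
  for (i in which(sel)) {
    j <- which(d1@intensity == s@intensity[i])
    if (length(j) == 1L) {
      delta <- abs(d1@mz[j] - s@mz[i])
      expect_gte(delta, 1 - 1e-9)
      expect_lte(delta, 30 + 1e-9)
    }
  }
  d3 <- makeDecoySpectrum(s, seed = 10)
  expect_false(isTRUE(all.equal(d1@mz, d3@mz)))
})

test_that("the e-value tail fit recovers an exponential rate", {
  lambda <- 1.7
  scores <- withRngSeed(101, stats::rexp(1e4, rate = lambda))
  model <- fitEvalueModel(scores)
  expect_true(model$valid)
  # survival is exp(-lambda x): slope of log10 S vs x = -lambda/ln(10)
  expect_equal(model$slope, -lambda / log(10), tolerance = 0.05)
  # e-values are monotone non-increasing in score
  ev <- evalueOf(model, c(0.5, 1, 2, 4))
  expect_true(all(diff(ev) <= 0))
  expect_error(fitEvalueModel(c(1, 2, 3)), "at least 10")
})

test_that("the expansion FDR formula counts decoys twice", {
  mk <- function(nT, nD) data.frame(
    evalue = seq_len(nT + nD) * 1e-3,
    decoy = c(rep(FALSE, nT), rep(TRUE, nD)),
    m = 6L, y1Matched = TRUE, glycanMass = 100)
  f1 <- expansionFdr(mk(99, 1))
  expect_equal(max(f1$fdr), 2 * 1 / (1 + 99))
  f2 <- expansionFdr(mk(50, 0))
  expect_equal(unique(f2$fdr), 0)
  f3 <- expansionFdr(mk(10, 10))
  expect_equal(max(f3$fdr), 1.0)
})

test_that("expansion recovers fragment-suppressed glycoforms", {
  run <- corruptRun(simulateRun(simConfig(seed = 7, nPeptides = 5L,
                                          glycansPerSite = 3L,
                                          scansPerGlycoform = 4L,
                                          noisePeaks = 8L)),
                    "drop_by", fraction = 0.4, seed = 3)
  res <- runPipeline(run$ms2, run$index, run$glycanDb,
                     runConfig(seed = 5))
  acc <- res$expansionAccepted
  m <- merge(acc, run$truth, by = "scanId")
  expect_true(all(m$peptide.x == m$peptide.y))
  supp <- run$truth$scanId[run$truth$suppressed]
  expect_gte(sum(m$scanId %in% supp) / length(supp), 0.9)
})

test_that("spectra outside the RT window or lacking Y1 are rejected", {
  run <- smallRun(seed = 3)
  tr <- run$truth[1, ]
  s <- run$ms2[[1]]
  pepRow <- list(peptide = tr$peptide, modPos = tr$modPos,
                 modMass = tr$modMass, mass = tr$pepMass)
  avg <- extractPattern(s, tr$peptide, tolPpm = 20)
  far <- ms2Spectrum("far", s@precursorMz, s@precursorCharge,
                     s@rt + 2500, s@mz, s@intensity)
  ex <- expandPeptide(pepRow, avg, list(far))
  expect_false("far" %in% ex$scanId)
  # strip the Y1 peak: the match may score but cannot be accepted
  y1mz <- (tr$pepMass + HEXNAC + PROTON)
  keep <- abs(s@mz - y1mz) > 0.05 &
    abs(s@mz - (tr$pepMass + HEXNAC + 2 * PROTON) / 2) > 0.05
  noY1 <- ms2Spectrum("noY1", s@precursorMz, s@precursorCharge, s@rt,
                      s@mz[keep], s@intensity[keep])
  ex2 <- expandPeptide(pepRow, avg, rep(list(noY1), 6))
  if (nrow(ex2)) expect_false(any(ex2$accepted[ex2$scanId == "noY1"]))
})
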