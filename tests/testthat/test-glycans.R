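test_that("topology parsing and the canonical fallback are consistent", {
  t <- parseGlycanTopology("pep(HexNAc(HexNAc(Hex(Hex)(Hex))))")
  expect_equal(nrow(t), 5L)
  expect_equal(sum(t$parent == 0L), 1L)
  expect_equal(as.vector(table(t$name)[c("Hex", "HexNAc")]), c(3, 2))
  expect_error(parseGlycanTopology("HexNAc(Hex)"), "rooted at 'pep'")
  # fallback node multiset equals the composition
  for (comp in c("Hex(5)HexNAc(2)", "Hex(5)HexNAc(4)NeuAc(2)",
                 "Hex(3)HexNAc(2)", "Hex(5)HexNAc(4)Fuc(1)NeuAc(1)",
                 "Hex(9)HexNAc(2)")) {
    topo <- canonicalTopology(comp)
    cnt <- glycanCounts(parseGlycanComposition(comp))
    expect_equal(sort(as.vector(table(topo$name)[names(cnt)])),
                 sort(as.vector(cnt)), info = comp)
    # exactly one root, every parent exists
    expect_equal(sum(topo$parent == 0L), 1L, info = comp)
    expect_true(all(topo$parent %in% c(0L, topo$node)), info = comp)
  }
})

test_that("B/Y enumeration equals brute-force single-cut masses", {
  topoStr <- "pep(HexNAc(Fuc)(HexNAc(Hex(Hex(HexNAc))(Hex))))"
  topo <- parseGlycanTopology(topoStr)
  pepMass <- 1000
  frag <- theoreticalGlycanFragments(
    list(composition = "Hex(3)HexNAc(3)Fuc(1)", topology = topoStr),
    pepMass, maxCharge = 1L)
  # brute force: subtree compositions by hand for each of 7 edges
  monos <- monosaccharideMasses()
  subtrees <- list(
    c(Hex = 3, HexNAc = 3, Fuc = 1),        # cut at root HexNAc
    c(Fuc = 1),
    c(Hex = 3, HexNAc = 2),                  # second HexNAc subtree
    c(Hex = 3, HexNAc = 1),                  # branch Hex subtree
    c(Hex = 1, HexNAc = 1),                  # arm with antenna
    c(HexNAc = 1),                           # antenna HexNAc
    c(Hex = 1))                              # other arm
  total <- sum(monos[c("Hex", "HexNAc", "Fuc")] * c(3, 3, 1))
  wantY <- sort(unique(round(
    pepMass + total - vapply(subtrees, function(s)
      sum(monos[names(s)] * s), numeric(1)) + PROTON, 4)))
  gotY <- sort(unique(round(frag$mz[frag$kind == "Y" &
                                      frag$label != "Y-intact"], 4)))
  expect_equal(gotY, wantY)
  # a linear chain over the core shows all six canonical core Y ions
  lin <- "pep(HexNAc(HexNAc(Hex(Hex(Hex(Hex(Hex)))))))"
  fragLin <- theoreticalGlycanFragments(
    list(composition = "Hex(5)HexNAc(2)", topology = lin), pepMass,
    maxCharge = 1L)
  off <- c(0, HEXNAC, 2 * HEXNAC, HEX + 2 * HEXNAC,
           2 * HEX + 2 * HEXNAC, 3 * HEX + 2 * HEXNAC)
  for (o in off)
    expect_true(any(abs(fragLin$mz - (pepMass + o + PROTON)) < 1e-3))
  # inconsistent topology is skipped with a warning
  expect_warning(bad <- theoreticalGlycanFragments(
    list(composition = "Hex(9)HexNAc(2)", topology = lin), pepMass),
    "inconsistent")
  expect_null(bad)
})

test_that("database annotation picks the supported composition", {
  db <- glycanDbFromCompositions(c("Hex(5)HexNAc(2)",
                                   "Hex(6)HexNAc(2)",
                                   "Hex(4)HexNAc(3)"))
  pepMass <- 1200.6
  frag <- theoreticalGlycanFragments(
    list(composition = "Hex(5)HexNAc(2)", topology = ""), pepMass,
    maxCharge = 2L)
  s <- ms2Spectrum("s", (pepMass + 1216.4229 + 2 * PROTON) / 2, 2L,
                   10, sort(frag$mz),
                   rep(50, nrow(frag))[order(frag$mz)])
  hit <- annotateFromDb(s, pepMass, 1216.4229, db)
  expect_equal(glycanLabel(hit$composition), "Hex(5)HexNAc(2)")
  expect_equal(hit$route, "database")
  # mass matching nothing in the db
  expect_null(annotateFromDb(s, pepMass, 4000.0, db))
  # isobaric candidates: Hex(2)HexNAc(2)Fuc(1) vs Hex(3)HexNAc(2)
  # differ by ~0.02 Da at wide tolerance; B/Y support decides
  db2 <- glycanDbFromCompositions(c("Hex(3)HexNAc(2)",
                                    "Hex(2)HexNAc(2)Fuc(1)"))
  fragA <- theoreticalGlycanFragments(
    list(composition = "Hex(2)HexNAc(2)Fuc(1)", topology = ""),
    pepMass, maxCharge = 1L)
  sB <- ms2Spectrum("s", 1500, 2L, 10, sort(fragA$mz),
                    rep(50, nrow(fragA))[order(fragA$mz)])
  hit2 <- annotateFromDb(sB, pepMass,
                         glycanMass("Hex(2)HexNAc(2)Fuc(1)"), db2,
                         tolDa = 0.1)
  expect_equal(glycanLabel(hit2$composition), "Hex(2)HexNAc(2)Fuc(1)")
})

test_that("Eq.2-style glycan scoring weights by frequency and alpha", {
  frag <- data.frame(kind = "Y", label = c("a", "b"),
                     mz = c(500, 700), charge = 1L)
  s <- ms2Spectrum("s", 1500, 2L, 10, c(500, 700), c(100, 50))
  expect_equal(scoreGlycan(s, frag)$score, 1 + 0.5^0.3,
               tolerance = 1e-9)
  expect_equal(scoreGlycan(s, frag, freq = c(1, 2))$score,
               1 + 0.25^0.3, tolerance = 1e-9)
  expect_equal(scoreGlycan(s, frag[frag$mz > 1000, ])$nMatched, 0L)
  one <- ms2Spectrum("s", 1500, 2L, 10, 500, 100)
  expect_equal(scoreGlycan(one, frag)$score, 1)
})

test_that("the stepping enumeration reproduces the 1395.50 example", {
  db <- glycanDbFromCompositions(c("Hex(6)HexNAc(2)",
                                   "Hex(5)HexNAc(2)Fuc(1)",
                                   "Hex(5)HexNAc(2)"))
  cand <- steppingCandidates(1395.50, db, moietyRange = c(1, 50))
  expect_equal(nrow(cand), 2L)
  expect_equal(round(sort(cand$moietyMass), 2), c(17.02, 33.02))
  expect_setequal(cand$composition,
                  c("Hex(6)HexNAc(2)", "Hex(5)HexNAc(2)Fuc(1)"))
})

test_that("stepping selects the route supported by the Y ladder", {
  db <- glycanDbFromCompositions(c("Hex(6)HexNAc(2)",
                                   "Hex(5)HexNAc(2)Fuc(1)"))
  pepMass <- 1000
  gMass <- glycanMass("Hex(6)HexNAc(2)") + 17.0265
  core <- 3 * HEX + 2 * HEXNAC
  # full Hex ladder from the core to H6N2, then the moiety terminal
  chain <- pepMass + core + cumsum(c(0, HEX, HEX, HEX, 17.0265))
  mz <- c(204.0867, 138.0549, 366.1395, chain + PROTON)
  s <- ms2Spectrum("s", (pepMass + gMass + 2 * PROTON) / 2, 2L, 10,
                   mz, rep(50, length(mz)))
  hit <- monosaccharideStepping(s, pepMass, gMass, db)
  expect_equal(sub("\\+.*", "", glycanLabel(hit$composition)),
               "Hex(6)HexNAc(2)")
  expect_equal(hit$moietyMass, 17.0265, tolerance = 0.01)
  expect_gte(hit$routeCount, 1L)
  # base + moiety reproduces the observed glycan mass
  expect_equal(glycanMass(hit$composition), gMass, tolerance = 1e-6)
  # removing an intermediate Y ion breaks the only route
  broken <- ms2Spectrum("s", s@precursorMz, 2L, 10,
                        mz[-6], rep(50, length(mz) - 1)) # drop 2nd Hex
  expect_null(monosaccharideStepping(broken, pepMass, gMass, db))
})

test_that("precursor correction recovers the monoisotope", {
  run <- smallRun(seed = 37)
  tr <- run$truth[1, ]
  s <- run$ms2[[1]]
  pepEl <- peptideElements(tr$peptide)
  # already monoisotopic
  c0 <- correctPrecursor(s, tr$pepMass, pepEl, run$ms1)
  expect_equal(c0$offset, 0L)
  expect_true(c0$corrected)
  # picked at M+1
  sShift <- ms2Spectrum(scanId(s), s@precursorMz +
                          1.0033548 / s@precursorCharge,
                        s@precursorCharge, s@rt, s@mz, s@intensity)
  c1 <- correctPrecursor(sShift, tr$pepMass, pepEl, run$ms1)
  expect_equal(c1$offset, -1L)
  expect_equal(c1$mass, tr$pepMass + tr$glycanMass, tolerance = 0.01)
  # no MS1 coverage: passthrough with flag
  c2 <- correctPrecursor(s, tr$pepMass, pepEl, NULL)
  expect_false(c2$corrected)
  expect_equal(c2$mass, precursorMass(s))
})

test_that("glycan-level FDR separates real from shuffled spectra", {
  run <- simulateRun(simConfig(seed = 41, nPeptides = 5L,
                               glycansPerSite = 3L,
                               scansPerGlycoform = 1L,
                               noisePeaks = 10L))
  tr <- run$truth
  gpsms <- data.frame(scanId = tr$scanId, pepMass = tr$pepMass,
                      composition = sub("\\+.*", "", tr$glycan),
                      stringsAsFactors = FALSE)
  spectra <- setNames(run$ms2, tr$scanId)
  gpsms$glycanScore <- vapply(seq_len(nrow(gpsms)), function(i) {
    frag <- theoreticalGlycanFragments(
      list(composition = gpsms$composition[i], topology = ""),
      gpsms$pepMass[i], maxCharge = 2L)
    scoreGlycan(spectra[[gpsms$scanId[i]]], frag)$score
  }, numeric(1))
  out <- glycanFdr(gpsms, spectra, seed = 2)
  expect_gte(mean(out$glycanPass), 0.95)
  # identical seed gives identical flags
  out2 <- glycanFdr(gpsms, spectra, seed = 2)
  expect_identical(out$glycanPass, out2$glycanPass)
  # shuffled spectra: scores collapse and few if any pass
  shuffled <- lapply(run$ms2, makeDecoySpectrum, seed = 77)
  names(shuffled) <- tr$scanId
  gpsms3 <- gpsms
  gpsms3$glycanScore <- vapply(seq_len(nrow(gpsms3)), function(i) {
    frag <- theoreticalGlycanFragments(
      list(composition = gpsms3$composition[i], topology = ""),
      gpsms3$pepMass[i], maxCharge = 2L)
    scoreGlycan(shuffled[[gpsms3$scanId[i]]], frag)$score
  }, numeric(1))
  out3 <- glycanFdr(gpsms3, shuffled, seed = 2)
  expect_lte(mean(out3$glycanPass, na.rm = TRUE),
             mean(out$glycanPass))
  # too few GPSMs: indeterminate
  out4 <- glycanFdr(gpsms[1:3, ], spectra, seed = 2)
  expect_true(all(is.na(out4$glycanPass)))
})

test_that("glycans classify into the three composition categories", {
  expect_equal(classifyGlycan("Hex(5)HexNAc(2)")$class,
               "oligo-mannose")
  expect_equal(classifyGlycan("Hex(3)HexNAc(2)Fuc(1)")$class,
               "truncated")
  c1 <- classifyGlycan("Hex(5)HexNAc(4)NeuAc(2)")
  expect_equal(c1$class, "complex/hybrid")
  expect_equal(c1$subgroup, "sialylated, fucose-free")
  expect_equal(classifyGlycan("Hex(5)HexNAc(4)")$subgroup,
               "fucose- and sialic acid-free")
  expect_equal(classifyGlycan("Hex(5)HexNAc(4)Fuc(1)NeuAc(1)")$subgroup,
               "fucosylated and sialylated")
  expect_equal(classifyGlycan("Hex(4)HexNAc(3)Fuc(1)")$subgroup,
               "fucosylated, sialic acid-free")
})

test_that("mass profiles bin roughly and refine precisely", {
  masses <- c(rep(1216.4229, 5), rep(1378.4757, 3))
  prof <- buildMassProfiles(masses)
  expect_equal(sum(prof$rough$count), length(masses))
  expect_setequal(prof$rough$center, c(1216, 1378))
  expect_equal(prof$rough$count[prof$rough$center == 1216], 5L)
  withRngSeed(5, {
    cluster <- 179.079 + runif(50, -5e-4, 5e-4)
  })
  mp <- moietyProfile(cluster)
  expect_equal(mp$observation, 179.079, tolerance = 1e-3)
  p <- preciseMassBin(cluster)
  expect_equal(p$center, 179.079, tolerance = 1e-3)
  expect_equal(nrow(buildMassProfiles(numeric(0))$rough), 0L)
  # harmonisation snaps masses to their cluster centre
  harm <- harmonizeGlycanMasses(c(rep(1216.4229, 5), 1216.4260))
  expect_equal(length(unique(harm)), 1L)
})

test_that("the shipped composition table loads as a glycan database", {
  path <- system.file("extdata", "nglycan_compositions_synthetic.tsv",
                      package = "glycotandem")
  db <- readGlycanDb(path)
  expect_gt(nrow(db), 30L)
  expect_true(all(diff(db$mass) >= 0))
  expect_true("Hex(5)HexNAc(4)NeuAc(2)" %in% db$composition)
  # the explicit core topology entry fragments into the core ladder
  core <- db[db$topology != "", ][1, ]
  frag <- theoreticalGlycanFragments(core, 1000, maxCharge = 1L)
  expect_true(any(abs(frag$mz - (1000 + HEXNAC + PROTON)) < 1e-3))
})
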