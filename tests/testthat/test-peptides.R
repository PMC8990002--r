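test_that("digestion keeps only bounded sequon peptides", {
  idx <- digestProteome(c(P1 = "MKNGSAAAR"))
  expect_true("NGSAAAR" %in% idx$peptide)      # sequon NGS
  # X = P breaks the motif
  idx2 <- digestProteome(c(P1 = "MKNPSAAAR"))
  expect_false("NPSAAAR" %in% idx2$peptide)
  # a 5-residue sequon peptide fails the length bound
  idx3 <- digestProteome(c(P1 = "MKNGSTKAAAAAAR"),
                         maxMissedCleavages = 0L)
  expect_false("NGSTK" %in% idx3$peptide)
  # no cleavage before proline: the K-P bond stays intact
  idx4 <- digestProteome(c(P1 = "MKPNGSAAAR"))
  expect_false("PNGSAAAR" %in% idx4$peptide)
  expect_true("MKPNGSAAAR" %in% idx4$peptide)
})

test_that("digestion agrees with brute-force enumeration", {
  withRngSeed(29, {
    prot <- paste(sample(c("A", "G", "N", "S", "T", "K", "R", "L",
                           "P", "E"), 120, replace = TRUE),
                  collapse = "")
  })
  idx <- digestProteome(c(P = prot), maxOxidation = 0L)
  # oracle: all substrings bounded by cleavage sites (K/R not before
  # P), <= 3 missed cleavages, length/mass bounds, with a sequon
  aa <- strsplit(prot, "")[[1]]
  n <- length(aa)
  sites <- sort(unique(c(0, which((aa %in% c("K", "R")) &
                                    c(aa[-1] != "P", TRUE)), n)))
  oracle <- character(0)
  for (i in seq_along(sites)[-length(sites)]) {
    for (j in (i + 1):min(length(sites), i + 4)) {
      pep <- substr(prot, sites[i] + 1, sites[j])
      if (nchar(pep) < 6 || nchar(pep) > 40) next
      m <- peptideMass(pep)
      if (m < 600 || m > 4500) next
      if (grepl("N[^P][STC]", pep)) oracle <- c(oracle, pep)
    }
  }
  expect_setequal(idx$peptide, unique(oracle))
})

test_that("external PSM import filters q and sequons", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("scanId\tpeptide\tmods\tscore\tq",
               "s1\tNGSAAAR\t\t12\t0.001",
               "s2\tNGSAAAR\t2:15.9949\t10\t0.05",
               "s3\tNGSAAAR\t\t11\t0.009",
               "s4\tAAAAAAK\t\t14\t0.001"), path)
  expect_warning(psms <- loadInitialPsms(path), "sequon")
  expect_equal(nrow(psms), 2L)          # q filter drops s2, sequon s4
  expect_setequal(psms$scanId, c("s1", "s3"))
  # unparseable mod string: row-level warning, others load
  writeLines(c("scanId\tpeptide\tmods\tscore\tq",
               "s1\tNGSAAAR\tbad:mod:x\t12\t0.001",
               "s2\tNGSAAAR\t\t10\t0.001"), path)
  expect_warning(psms2 <- loadInitialPsms(path), "row 1")
  expect_equal(psms2$scanId, "s2")
  # empty file
  writeLines(character(0), path)
  expect_equal(nrow(loadInitialPsms(path)), 0L)
  # missing column
  writeLines(c("scanId\tpeptide", "s1\tNGSAAAR"), path)
  expect_error(loadInitialPsms(path), "lacks column")
})

test_that("the built-in search identifies noise-free simulations", {
  run <- simulateRun(simConfig(seed = 13, nPeptides = 5L,
                               glycansPerSite = 2L,
                               scansPerGlycoform = 2L,
                               noisePeaks = 0L))
  deg <- deglycosylateRun(run$ms2)
  psms <- builtinSearch(deg$spectra, run$index)
  m <- merge(psms, run$truth, by.x = "sourceScan", by.y = "scanId")
  expect_equal(nrow(m), length(run$ms2))
  expect_true(all(m$peptide.x == m$peptide.y))
  expect_true(all(m$q < 0.01))
})

test_that("searching a wrong-sequence index yields no confident PSMs", {
  run <- smallRun(seed = 17)
  deg <- deglycosylateRun(run$ms2)
  shuffled <- run$index
  withRngSeed(1, {
    shuffled$peptide <- vapply(shuffled$peptide, function(p) {
      a <- strsplit(p, "")[[1]]
      n <- length(a)
      paste(c(sample(a[-n]), a[n]), collapse = "")
    }, character(1))
  })
  # keep only scrambled sequences that are genuinely different
  shuffled <- shuffled[shuffled$peptide != run$index$peptide, ,
                       drop = FALSE]
  psms <- builtinSearch(deg$spectra, shuffled)
  expect_true(nrow(psms) == 0L || all(psms$q >= 0.01) ||
                mean(psms$q < 0.01) < 0.1)
})

test_that("decoy index reverses sequences keeping the terminus", {
  idx <- digestProteome(c(P1 = "MKNGSTAAWR"))
  dec <- decoyPeptideIndex(idx)
  expect_equal(nrow(dec), nrow(idx))
  expect_true(all(substr(dec$peptide, nchar(dec$peptide),
                         nchar(dec$peptide)) ==
                    substr(idx$peptide[order(idx$mass)],
                           nchar(idx$peptide), nchar(idx$peptide))))
  expect_equal(sort(dec$mass), sort(idx$mass))
})

test_that("mass queries hit the ppm window", {
  idx <- digestProteome(c(P1 = "MKNGSAAARNGTAAAK"))
  m <- idx$mass[1]
  expect_gte(nrow(queryPeptideIndex(idx, m, 10)), 1L)
  expect_equal(nrow(queryPeptideIndex(idx, m * (1 + 50e-6), 10)), 0L)
})
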