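test_that("glycan masses match residue arithmetic", {
  expect_equal(glycanMass("Hex(3)HexNAc(2)"), 892.3172, tolerance = 1e-6)
  expect_equal(glycanMass(glycanComposition()), 0)
  expect_equal(round(glycanMass("Hex(6)HexNAc(2)"), 2), 1378.48)
  expect_equal(round(glycanMass("Hex(5)HexNAc(2)Fuc(1)"), 2), 1362.48)
  expect_equal(glycanMass(glycanComposition(Hex = 6, HexNAc = 2,
                                            moietyMass = 17.0265)),
               glycanMass("Hex(6)HexNAc(2)") + 17.0265)
  expect_error(glycanComposition(Xyz = 1), "unknown residue")
})

test_that("glycan mass is additive over compositions", {
  withRngSeed(42, {
    for (i in 1:20) {
      a <- glycanComposition(Hex = sample(0:9, 1),
                             HexNAc = sample(0:6, 1),
                             Fuc = sample(0:2, 1),
                             NeuAc = sample(0:3, 1))
      b <- glycanComposition(Hex = sample(0:9, 1),
                             HexNAc = sample(0:6, 1),
                             NeuGc = sample(0:2, 1))
      ab <- glycanCounts(a)
      bb <- glycanCounts(b)
      keys <- union(names(ab), names(bb))
      tot <- setNames(numeric(length(keys)), keys)
      tot[names(ab)] <- ab
      tot[names(bb)] <- tot[names(bb)] + bb
      expect_equal(glycanMass(a) + glycanMass(b),
                   glycanMass(glycanComposition(tot)),
                   tolerance = 1e-9)
    }
  })
})

test_that("composition strings parse and print canonically", {
  c1 <- parseGlycanComposition("Hex(5)HexNAc(2)")
  expect_equal(unname(glycanCounts(c1)[c("Hex", "HexNAc")]), c(5, 2))
  c2 <- parseGlycanComposition("Hex(6)HexNAc(2)+17.0265")
  expect_equal(moietyMass(c2), 17.0265)
  expect_equal(glycanLabel(c2), "Hex(6)HexNAc(2)+17.0265")
  # registry order is stable regardless of input order
  expect_equal(glycanLabel(glycanComposition(NeuAc = 1, Hex = 5,
                                             HexNAc = 4)),
               "Hex(5)HexNAc(4)NeuAc(1)")
  expect_error(parseGlycanComposition("Hex(5)garbage"), "parse")
})

test_that("peptide masses include water and modifications", {
  expect_equal(peptideMass("PEPTIDE"), 799.3600, tolerance = 1e-4)
  expect_equal(peptideMass("G"), 75.0320, tolerance = 1e-4)
  expect_equal(peptideMass("PEPTIDE", 57.02146), 856.3814,
               tolerance = 1e-4)
  # position of a modification does not change the total mass
  expect_equal(sum(residueMasses("PEPTIDE", 2L, 57.02146)),
               sum(residueMasses("PEPTIDE", 6L, 57.02146)))
  expect_error(peptideMass("PEPTIDEX"), "non-canonical")
  expect_error(peptideMass(""), "empty")
})

test_that("isotope patterns match natural-abundance expectations", {
  p <- isotopePattern(c(C = 1), nPeaks = 2)
  expect_equal(p$abundance[2] / p$abundance[1], 0.0107 / 0.9893,
               tolerance = 1e-6)
  w <- isotopePattern(c(H = 2, O = 1), nPeaks = 2)
  expect_equal(w$abundance[1], 1)
  expect_lt(w$abundance[2], 0.002)
  c100 <- isotopePattern(c(C = 100), nPeaks = 3)
  expect_equal(c100$abundance[2] / c100$abundance[1], 1.08,
               tolerance = 0.01)
})

test_that("isotope convolution matches the brute-force oracle", {
  cases <- list(c(C = 10, H = 20, O = 5),
                c(C = 34, H = 56, N = 2, O = 25),
                c(C = 120, H = 200, N = 30, O = 60, S = 2),
                c(C = 200, H = 250, N = 20, O = 29, S = 1))
  for (cc in cases) {
    got <- isotopePattern(cc, nPeaks = 6)$abundance
    want <- bruteIsotopePattern(cc, nPeaks = 6)
    expect_equal(got, want, tolerance = 1e-6)
  }
})

test_that("pseudo-glycan elements reproduce the target mass", {
  core <- pseudoGlycanElements(892.3172)
  expect_equal(attr(core, "hexUnits"), 0, tolerance = 1e-4)
  expect_equal(elementMass(core), 892.3172, tolerance = 1e-6)
  plus2 <- pseudoGlycanElements(1216.4229)
  expect_equal(attr(plus2, "hexUnits"), 2, tolerance = 1e-4)
  minus1 <- pseudoGlycanElements(730.264)
  expect_equal(attr(minus1, "hexUnits"), -1, tolerance = 1e-3)
  withRngSeed(3, {
    for (m in runif(10, 500, 4000))
      expect_equal(elementMass(pseudoGlycanElements(m)), m,
                   tolerance = 1e-6)
  })
  expect_error(pseudoGlycanElements(50), "too small")
  # fractional hex units interpolate between integer convolutions
  pFrac <- isotopePattern(pseudoGlycanElements(1000), nPeaks = 4)
  expect_equal(pFrac$abundance[1], 1)
  expect_true(all(pFrac$abundance >= 0))
})

test_that("the monosaccharide registry is extensible", {
  registerMonosaccharide("Pent", c(C = 5, H = 8, O = 4))
  expect_equal(unname(monosaccharideMasses()["Pent"]), 132.0423,
               tolerance = 1e-4)
  expect_equal(glycanMass(glycanComposition(Pent = 2)),
               2 * 132.04226, tolerance = 1e-4)
})
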