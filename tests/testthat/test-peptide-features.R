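mel <- PeptideRecord("melittin", ampPeptides()[["melittin"]])
ll37 <- PeptideRecord("LL37", ampPeptides()[["LL37"]])

test_that("residue counting respects the classification sets", {
  expect_identical(countResidues(mel, "cationic"), 5L)
  expect_identical(countResidues(mel, "anionic"), 0L)
  expect_identical(countResidues(ll37, "cationic"), 11L)
  empty <- PeptideRecord("x", "GIGA", cationicSet = character(0))
  expect_identical(countResidues(empty, "cationic"), 0L)
  expect_error(PeptideRecord("bad", "GIGX"), "position 4")
  expect_error(PeptideRecord("bad", ""), "non-empty")
})

test_that("protofibril pitch is monomers per turn times rise", {
  expect_equal(protofibrilGeometry(4, 0.82)$pitch, 3.28)
  expect_equal(protofibrilGeometry(4, 1.7)$pitch, 6.8)
  expect_error(protofibrilGeometry(4, 0), "risePerMonomer")
})

test_that("axial charge density reproduces the per-turn bookkeeping", {
  # 5 K/R per monomer, 0.82 nm rise: 20.7 per 3.4 nm, rounding to 21
  dens <- axialChargeDensity(mel, protofibrilGeometry(4, 0.82))
  expect_equal(dens$density, 5 * 3.4 / 0.82, tolerance = 1e-12)
  expect_identical(dens$rounded, 21)
  # rise equal to the window: one monomer's worth of charge
  expect_equal(axialChargeDensity(mel,
                                  protofibrilGeometry(4, 3.4))$density, 5)
  # 11 K/R at a 1.7 nm rise gives 22 per window
  expect_equal(axialChargeDensity(ll37,
                                  protofibrilGeometry(4, 1.7))$density, 22)
})

test_that("axial density is linear in window and cationic count", {
  g <- protofibrilGeometry(4, 0.82)
  d1 <- axialChargeDensity(mel, g, window = 3.4)$density
  d2 <- axialChargeDensity(mel, g, window = 6.8)$density
  expect_equal(d2, 2 * d1, tolerance = 1e-12)
  doubled <- PeptideRecord("kk", paste0(peptideSequence(mel),
                                        strrep("K", 5)))
  expect_equal(axialChargeDensity(doubled, g)$density, 2 * d1,
               tolerance = 1e-12)
})

test_that("DNA charge density defaults to 20 per helical turn", {
  expect_equal(dnaChargeDensity(), 20, tolerance = 1e-15)
  expect_equal(dnaChargeDensity(window = 0.34), 2)
  expect_equal(dnaChargeDensity(chargesPerBp = 1), 10)
})

test_that("hydrophobic fractions bracket the expected range", {
  expect_equal(hydrophobicFraction(mel), 10 / 26, tolerance = 1e-12)
  expect_gte(hydrophobicFraction(mel), 0.30)
  expect_lte(hydrophobicFraction(mel), 0.45)
  expect_gte(hydrophobicFraction(ll37), 0.30)
  expect_lte(hydrophobicFraction(ll37), 0.45)
  allhyd <- PeptideRecord("x", "LLLVVV")
  expect_equal(hydrophobicFraction(allhyd), 1)
  none <- PeptideRecord("x", "GGSS", hydrophobicSet = character(0))
  expect_equal(hydrophobicFraction(none), 0)
})

test_that("face angle handles saturation and empty cases", {
  # 18 residues, all hydrophobic: angles tile the wheel every 20 degrees,
  # so the wheel is fully covered
  sat <- PeptideRecord("sat", strrep("L", 18))
  expect_equal(hydrophobicFaceAngle(sat), 360)
  polar <- PeptideRecord("pol", "GSGSGSGS")
  expect_equal(hydrophobicFaceAngle(polar), 0)
})

test_that("a constructed semicircle pattern gives a 180-degree-class face", {
  # place L at wheel angles 0, 40, 80, 120, 160 (positions 1, 5, 9, 13,
  # 17 at 100 degrees/residue): hydrophobic arc of 160, gap of 200
  seqv <- rep("S", 17)
  seqv[c(1, 5, 9, 13, 17)] <- "L"
  rec <- PeptideRecord("semi", paste(seqv, collapse = ""))
  expect_equal(hydrophobicFaceAngle(rec), 160)
})

test_that("face angle equals the brute-force minimal covering sector", {
  set.seed(5)
  for (i in 1:25) {
    n <- sample(8:40, 1)
    seqv <- sample(c("L", "S"), n, replace = TRUE,
                   prob = c(0.4, 0.6))
    if (!any(seqv == "L")) seqv[1] <- "L"
    rec <- PeptideRecord("r", paste(seqv, collapse = ""))
    ang <- (which(seqv == "L") - 1) * 100
    expected <- bruteFaceSector(ang)
    got <- hydrophobicFaceAngle(rec)
    # skip the uniform-coverage convention, tested separately above
    gaps <- diff(c(sort(unique(ang %% 360)),
                   min(sort(unique(ang %% 360))) + 360))
    if (length(unique(ang %% 360)) > 1 && max(gaps) > 20)
      expect_equal(got, round(expected), info = paste(seqv, collapse = ""))
  }
})

test_that("face angle is invariant under wheel rotation", {
  # prepending polar residues shifts every angle by the same offset
  base <- "SSLLSSLSSSLSS"
  a1 <- hydrophobicFaceAngle(PeptideRecord("a", base))
  a2 <- hydrophobicFaceAngle(PeptideRecord("b", paste0("S", base)))
  expect_equal(a1, a2)
})

test_that("segments restrict the wheel to part of the helix", {
  rec <- PeptideRecord("seg", "LLLLSSSSSSSSSSSSSSSSSSSSSSLLLL")
  whole <- hydrophobicFaceAngle(rec)
  head4 <- hydrophobicFaceAngle(rec, segment = c(1, 4))
  expect_lte(head4, whole)
  expect_error(hydrophobicFaceAngle(rec, segment = c(1, 50)), "within")
  expect_error(hydrophobicFaceAngle(rec, segment = c(1, 3)), "at least 4")
})

test_that("the peptide report names its hydrophobic set", {
  rep <- peptideReport(list(mel, ll37),
                       geometry = protofibrilGeometry(4, 0.82))
  expect_identical(nrow(rep), 2L)
  expect_identical(attr(rep, "hydrophobicSet"), "LIVFMWC")
  expect_equal(rep$axialDensity[1], 20.7, tolerance = 0.01)
})
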