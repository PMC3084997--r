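test_that("amino-acid frequencies exclude ambiguity letters and sum to 1", {
  f <- aa_frequencies("AAAA")
  expect_equal(unname(f["aa_A"]), 1.0)
  expect_equal(sum(f), 1.0)
  expect_equal(unname(aa_frequencies("ACDE")), rep(0.25, 20) *
                 (amino_acids() %in% c("A", "C", "D", "E")))
  expect_equal(unname(aa_frequencies("AXA")["aa_A"]), 1.0)
  expect_error(aa_frequencies("XXX"), "no standard residue")
  for (seed in 1:20) {
    s <- random_sequence(sample(2:500, 1), seed)
    expect_equal(sum(aa_frequencies(s)), 1, tolerance = 1e-9)
    expect_equal(sum(dipeptide_frequencies(s)), 1, tolerance = 1e-9)
  }
})

test_that("dipeptide frequencies count overlapping pairs and skip ambiguity", {
  d <- dipeptide_frequencies("ACAC")
  expect_equal(unname(d["dp_AC"]), 2 / 3)
  expect_equal(unname(d["dp_CA"]), 1 / 3)
  expect_equal(sum(d), 1)
  expect_equal(sum(dipeptide_frequencies("A")), 0)
  expect_equal(sum(dipeptide_frequencies("AXC")), 0)
})

test_that("bisection pI zeroes the charge curve and matches the grid oracle", {
  s <- "ACDEFGHIKLMNPQRSTVWY"
  expect_lt(abs(peptide_charge(s, isoelectric_point(s))), 1e-3)
  expect_gt(isoelectric_point("KKKK"), 7)
  expect_lt(isoelectric_point("DDDD"), 7)
  for (seed in 1:50) {
    pep <- random_sequence(10, seed + 100)
    expect_lt(abs(isoelectric_point(pep) - brute_pi(pep)), 0.01)
  }
})

test_that("mean GES hydrophobicity is the table mean over standard residues", {
  ges <- ges_scale()
  for (r in c("F", "R", "G"))
    expect_identical(mean_ges_hydrophobicity(strrep(r, 7)), unname(ges[r]))
  expect_equal(mean_ges_hydrophobicity("FM"), (ges[["F"]] + ges[["M"]]) / 2)
  s <- random_sequence(60, seed = 3)
  shuffled <- paste(sample(strsplit(s, "")[[1]]), collapse = "")
  expect_equal(mean_ges_hydrophobicity(s), mean_ges_hydrophobicity(shuffled))
})

test_that("molecular weight is additive and imputes ambiguity with the mean mass", {
  expect_equal(molecular_weight("GG"), 132.12, tolerance = 0.01)
  s <- random_sequence(30, seed = 4)
  expect_gt(molecular_weight(paste0(s, "W")), molecular_weight(s))
  expect_equal(molecular_weight("ACDE"),
               molecular_weight("AC") + molecular_weight("DE") - 18.01528)
  expect_equal(molecular_weight("X"),
               mean(residue_masses()) + 18.01528)
})

test_that("heuristic annotators are deterministic, length-preserving masks", {
  for (seed in 1:10) {
    s <- random_sequence(sample(30:200, 1), seed + 50)
    for (k in c("helix", "strand", "disorder", "transmembrane")) {
      m1 <- heuristic_annotate(s, k)
      expect_length(m1, nchar(s))
      expect_true(all(m1 %in% c(0L, 1L)))
      expect_identical(m1, heuristic_annotate(s, k))
    }
  }
  # all-Gly mean GES (1.0) is below the 1.6 kcal/mol threshold
  expect_true(all(heuristic_annotate(strrep("G", 50), "transmembrane") == 0))
  # a strongly hydrophobic stretch is flagged
  expect_true(any(heuristic_annotate(
    paste0(strrep("G", 30), strrep("L", 25), strrep("G", 30)),
    "transmembrane") == 1))
  expect_error(heuristic_annotate("ACDE", "coil"))
})

test_that("helix/strand heuristics erase runs shorter than four residues", {
  for (k in c("helix", "strand")) {
    m <- heuristic_annotate(random_sequence(300, seed = 9), k)
    runs <- rle(as.vector(m))
    expect_true(all(runs$lengths[runs$values == 1] >= 4))
  }
})

test_that("assembled feature vectors have 428 entries scaled to [0,1]", {
  for (seed in 1:25) {
    s <- random_sequence(sample(10:2000, 1), seed,
                         alphabet = c(amino_acids(), "X"))
    if (!grepl("[ACDEFGHIKLMNPQRSTVWY]", s)) next
    f <- assemble_features(s)
    expect_length(f, 428)
    expect_identical(names(f), feature_names())
    expect_true(all(f >= 0 & f <= 1))
  }
})

test_that("assemble_features is pure and permutations differ only where expected", {
  s <- random_sequence(80, seed = 11)
  tr <- all_tracks(s)
  expect_identical(assemble_features(s, tr), assemble_features(s, tr))
  perm <- paste(rev(strsplit(s, "")[[1]]), collapse = "")
  f1 <- assemble_features(s, tr)
  f2 <- assemble_features(perm, tr)  # same tracks: annotation entries fixed
  comp_only <- c(paste0("aa_", amino_acids()), "pI", "mean_ges", "length",
                 "mol_weight", "frac_helix", "frac_strand", "frac_disorder",
                 "frac_tm")
  expect_equal(f1[comp_only], f2[comp_only])
  expect_false(isTRUE(all.equal(f1, f2)))  # dipeptides do change
})

test_that("track length mismatches are rejected", {
  s <- "ACDEFGHIKL"
  tr <- all_tracks(s)
  tr$helix <- tr$helix[-1]
  expect_error(assemble_features(s, tr), "length")
})
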