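test_that("element composition algebra is element-wise and guards negatives", {
  a <- element_composition(C = 2, H = 4, O = 1)
  b <- element_composition(H = 2, O = 1)
  expect_true((a + b) == element_composition(C = 2, H = 6, O = 2))
  expect_true((a - b) == element_composition(C = 2, H = 2))
  expect_error(b - a, "negative")
  expect_error(element_composition(C = -1), "non-negative")
  # equality ignores storage order and zero entries
  expect_true(element_composition(O = 1, H = 2) == parse_formula("H2O"))
})

test_that("Hill-order rendering and formula parsing round-trip", {
  comp <- element_composition(N = 18, O = 23, C = 84, H = 146)
  expect_identical(hill_formula(comp), "C84H146N18O23")
  expect_true(parse_formula(hill_formula(comp)) == comp)
  expect_identical(hill_formula(parse_formula("H2O")), "H2O")
  # implicit count of one
  expect_identical(hill_formula(parse_formula("C2H5NO2")), "C2H5NO2")
  expect_error(parse_formula("notaformula!"), "parse")
})

test_that("residue registry covers the vocabulary and rejects raw Glx", {
  known <- known_residues()
  expect_true(all(c("aThr", "Dhb", "Dab", "OH-Asp", "Glx", "Xle") %in% known))
  expect_length(setdiff(known, c("Glx", "Xle")), 24)
  expect_error(residue_composition("Glx"), "ambiguity")
  expect_error(residue_composition("Zzz"), "unknown")
  # chain residue = free amino acid minus water
  gly_free <- compose_formula(lipopeptide_structure("Gly"))
  expect_identical(hill_formula(gly_free), "C2H5NO2")
})

test_that("compose_formula reproduces the printed congener formulas exactly", {
  tab <- read_congener_table(tt_extdata("congeners_xantholysin.tsv"))
  expected <- c(xantholysin_A = "C84H146N18O23",
                xantholysin_B = "C83H144N18O23",
                xantholysin_C = "C86H148N18O23")
  for (nm in names(expected)) {
    st <- structure_from_congener(tab[tab$name == nm, ])
    expect_identical(hill_formula(compose_formula(st)), expected[[nm]],
                     label = nm)
  }
})

test_that("monoisotopic masses match independent summation", {
  # frozen values cross-checked against an independent mass calculator
  expect_equal(monoisotopic_mass("H2O", digits = 4), 18.0106)
  expect_equal(monoisotopic_mass("C2H5NO2", digits = 4), 75.0320)
  expect_equal(monoisotopic_mass("C84H146N18O23", digits = 4), 1775.0808)
  expect_error(monoisotopic_mass(element_composition(Zz = 1)), "unknown")
})

test_that("adduct m/z uses the proton mass and decreases with charge", {
  expect_equal(adduct_mz("C84H146N18O23", "[M+H]+"), 1776.0881)
  expect_equal(adduct_mz("C83H144N18O23", "[M+H]+"), 1762.0724)
  expect_equal(adduct_mz("C84H146N18O23", "[M+2H]2+"),
               round((1775.08082 + 2 * 1.007276) / 2, 4), tolerance = 1e-4)
  mzs <- vapply(1:4, function(z) {
    adduct_mz("C84H146N18O23", sprintf("[M+%dH]%d+", z, z), digits = NULL)
  }, numeric(1))
  expect_true(all(diff(mzs) < 0))
  expect_gt(adduct_mz("C84H146N18O23", "[M+Na]+"),
            adduct_mz("C84H146N18O23", "[M+H]+"))
  expect_error(adduct_mz("H2O", "[M+H]0+"), "parse|charge")
})

test_that("mass deltas map to the expected congener hypotheses", {
  hit14 <- mass_delta_explain(14.02, 0.05)
  expect_identical(hit14$delta_formula[1], "CH2")
  expect_match(hit14$interpretation[1], "Ile<->Val")
  hit26 <- mass_delta_explain(26.02, 0.05)
  expect_identical(hit26$delta_formula[1], "C2H2")
  expect_match(hit26$interpretation[1], "C10:0 -> C12:1")
  id <- mass_delta_explain(0, 0.05)
  expect_identical(id$delta_formula, "none")
  expect_identical(nrow(mass_delta_explain(7.77, 0.01)), 0L)
  # ranking by |error| and extensibility via a user table
  ext <- rbind(mass_delta_table(),
               data.frame(delta_formula = "O", delta_mass = 15.9949,
                          interpretation = "oxidation"))
  expect_identical(mass_delta_explain(16, 0.1, table = ext)$delta_formula[1], "O")
})

test_that("lactonization and acylation identities hold over random structures", {
  set.seed(2024)
  for (i in 1:25) {
    n <- sample(4:16, 1)
    cyc <- tt_random_structure(n)
    lin <- cyc
    lin$lactone_donor <- NULL
    expect_equal(monoisotopic_mass(compose_formula(lin)) -
                   monoisotopic_mass(compose_formula(cyc)),
                 18.0106, tolerance = 1e-4)
    free <- lin
    free$fatty_acid <- NULL
    expect_true(
      (compose_formula(lin) - compose_formula(free)) ==
        (fatty_acid_composition(lin$fatty_acid) - parse_formula("H2O")))
  }
})

test_that("lactone donors must carry a hydroxyl", {
  expect_error(lipopeptide_structure(c("Leu", "Val"), lactone_donor = 1),
               "hydroxyl")
  expect_silent(lipopeptide_structure(c("Thr", "Val"), lactone_donor = 1))
  expect_error(lipopeptide_structure("Ser", lactone_donor = 3))
})

test_that("Glx enumeration reports a 0.984 Da spread per residue", {
  st <- lipopeptide_structure(c("Leu", "Glx", "Glx", "Ser"))
  expect_error(compose_formula(st), "ambiguity")
  sp <- glx_mass_spread(st)
  expect_identical(sp$n_glx, 2L)
  expect_equal(sp$spread, 2 * 0.98402, tolerance = 1e-4)
})

test_that("fatty-acid compositions follow CnH(2n-2d)O3", {
  expect_identical(hill_formula(fatty_acid_composition(fatty_acid_spec(10))),
                   "C10H20O3")
  c12_1 <- parse_fatty_acid("C12:1(5c)-3OH")
  expect_identical(hill_formula(fatty_acid_composition(c12_1)), "C12H22O3")
  expect_identical(c12_1$double_bonds[[1]]$geometry, "cis")
  expect_identical(format(c12_1), "C12:1(5c)-3OH")
  expect_error(parse_fatty_acid("decanoate"), "parse")
  expect_error(fatty_acid_spec(1), "carbons")
})
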