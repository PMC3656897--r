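mock_call <- function(label, ties = label) {
  structure(list(domain_id = label, label = label, method = "signature-NN",
                 score = 10, ties = ties, confidence = "confident"),
            class = "specificity_call")
}

mock_line <- function(n, te_tandem = TRUE) {
  structure(list(modules = data.frame(module = seq_len(n)),
                 has_starter_c = TRUE, te_tandem = te_tandem),
            class = "assembly_line")
}

xtl_labels <- c("Leu", "Glu", "Gln", "Val", "Leu", "Gln", "Ser",
                "Val", "Leu", "Gln", "Leu", "Leu", "Gln", "Ile")

test_that("co-linearity maps one call per module onto the peptide", {
  calls <- lapply(xtl_labels, mock_call)
  calls[[14]] <- mock_call("Ile", ties = c("Ile", "Val"))
  pred <- predict_peptide(mock_line(14), calls)
  expect_identical(pred$residues, xtl_labels)
  expect_identical(pred$alternatives[[14]], "Val")
  expect_length(pred$alternatives[[1]], 0)
  expect_error(predict_peptide(mock_line(14), calls[1:13]), "one substrate call")
  one <- predict_peptide(mock_line(1), list(mock_call("Gly")))
  expect_identical(one$residues, "Gly")
})

test_that("the dual C/E rule sets stereochemistry of the preceding residue", {
  expect_identical(as.character(assign_stereochemistry(
    c("starter", "conventional", "conventional"))), c("L", "L", "L"))
  # xantholysin-like plan: C/E at modules 2-11 and 14, conventional at 12-13
  plan <- c("starter", rep("C/E", 10), "conventional", "conventional", "C/E")
  st <- assign_stereochemistry(plan)
  expect_identical(as.character(st),
                   c(rep("D", 10), "L", "L", "D", "L"))
  expect_match(attr(st, "caveat"), "predicted")
  # unassigned subtype leaves the affected residue unknown
  st2 <- assign_stereochemistry(c("starter", "unassigned", "C/E"))
  expect_identical(as.character(st2), c("unknown", "D", "L"))
})

test_that("cyclization enumeration finds every internal hydroxyl donor", {
  xan <- enumerate_cyclization(xtl_labels, te_present = TRUE)
  expect_identical(nrow(xan), 1L)
  expect_identical(xan$donor, 7L)
  expect_identical(xan$ring_size, 8L)   # octacyclic closure

  etl <- c("Leu", "Glu", "Gln", "Val", "Leu", "Gln", "Val", "Leu", "Gln",
           "Ser", "Val", "Leu", "Ser", "Ile")
  cand <- enumerate_cyclization(etl, te_present = TRUE)
  expect_identical(cand$donor, c(10L, 13L))
  expect_identical(cand$ring_size, c(5L, 2L))  # pentacyclic form is validated

  expect_identical(nrow(enumerate_cyclization(c("Leu", "Val"), TRUE)), 0L)
  expect_identical(nrow(enumerate_cyclization(xtl_labels, FALSE)), 0L)
  # a C-terminal hydroxyl residue cannot close onto itself
  expect_identical(nrow(enumerate_cyclization(c("Leu", "Ser"), TRUE)), 0L)
  expect_identical(enumerate_cyclization(c("Ser", "Leu"), TRUE)$ring_size, 2L)
})

test_that("congener enumeration spans residues x fatty acids with correct masses", {
  calls <- lapply(xtl_labels, mock_call)
  calls[[14]] <- mock_call("Ile", ties = c("Ile", "Val"))
  pred <- predict_peptide(mock_line(14), calls)
  fas <- list(fatty_acid_spec(10),
              fatty_acid_spec(12, list(list(position = 5, geometry = "cis"))))
  cong <- enumerate_congeners(pred, fas, cyclization = 7)
  expect_identical(nrow(cong), 4L)
  expect_identical(cong$name[1], "primary")
  expect_identical(cong$formula[1], "C84H146N18O23")          # xantholysin A
  expect_true("C83H144N18O23" %in% cong$formula)              # B (Val14)
  expect_true("C86H148N18O23" %in% cong$formula)              # C (C12:1)
  # nominal congener deltas
  mA <- cong$monoisotopic_mass[cong$formula == "C84H146N18O23"][1]
  mB <- cong$monoisotopic_mass[cong$formula == "C83H144N18O23"][1]
  mC <- cong$monoisotopic_mass[cong$formula == "C86H148N18O23"][1]
  expect_identical(round(mA - mB), 14)
  expect_identical(round(mC - mA), 26)

  solo <- enumerate_congeners(predict_peptide(mock_line(2), lapply(
    c("Ser", "Leu"), mock_call)), list(fatty_acid_spec(8)))
  expect_identical(nrow(solo), 1L)
})

test_that("congener count is the product of choices and fatty acids", {
  calls <- list(mock_call("Leu", c("Leu", "Ile")),
                mock_call("Ser"),
                mock_call("Val", c("Val", "Ile", "Leu")))
  pred <- predict_peptide(mock_line(3), calls)
  cong <- enumerate_congeners(pred, list(fatty_acid_spec(8),
                                         fatty_acid_spec(10)))
  expect_identical(nrow(cong), 2L * 1L * 3L * 2L)
})

test_that("depsi-site flagging reproduces the Ser downfield-shift logic", {
  rc <- random_coil_reference()
  shifts <- data.frame(residue_index = c(7, 7), atom = "HB",
                       shift_ppm = c(4.38, 4.58))
  res <- flag_depsi_sites(shifts, rc, site_residues = c(`7` = "Ser"))
  expect_true(res$flagged)
  expect_equal(res$deviation_ppm, 0.61, tolerance = 1e-6)

  at_rc <- data.frame(residue_index = c(7, 7), atom = "HB",
                      shift_ppm = c(3.79, 3.95))
  expect_false(flag_depsi_sites(at_rc, rc, c(`7` = "Ser"))$flagged)

  # the fatty-acid 3-OH site has no random-coil reference: skipped, so the
  # lipid hydroxyl is never flagged as the donor from shift evidence alone
  fa_site <- data.frame(residue_index = 0, atom = "HB", shift_ppm = 4.0)
  expect_warning(out <- flag_depsi_sites(fa_site, rc, c(`7` = "Ser")),
                 "skipped")
  expect_identical(nrow(out), 0L)
})

test_that("alkene geometry follows the flanking 13C shift signs", {
  expect_identical(classify_alkene_geometry(35.53 - 37.91, 27.28 - 29.60),
                   "cis")
  expect_identical(classify_alkene_geometry(39.1 - 36.8, 33.7 - 29.3),
                   "trans")
  expect_identical(classify_alkene_geometry(-1, 1), "ambiguous")
  expect_error(classify_alkene_geometry(NA, 1), "finite")
})

test_that("peptide length equals module count over synthetic lines", {
  set.seed(401)
  for (i in 1:10) {
    n_prot <- sample(1:3, 1)
    plan <- sample(1:5, n_prot, replace = TRUE)
    cfg <- sim_config(seed = 500 + i, modules_per_protein = plan)
    sim <- simulate_assembly_line(cfg)
    expect_length(sim$truth$peptide, sum(plan))
    expect_length(sim$truth$stereo, sum(plan))
    # D residues are exactly the residues preceding a C/E module
    expect_identical(sum(sim$truth$stereo == "D"),
                     sum(cfg$c_subtype_plan[-1] == "C/E"))
    cyc <- sim$truth$cyclization
    if (nrow(cyc)) {
      expect_true(all(cyc$ring_size >= 2 & cyc$ring_size <= sum(plan)))
    }
  }
})
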