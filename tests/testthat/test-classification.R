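test_that("signature extraction is exact on the template and robust to insertions", {
  tpl <- signature_template()
  chars <- strsplit(tpl$anchor_sequence, "")[[1]]
  own34 <- paste0(chars[tpl$idx34], collapse = "")
  own10 <- paste0(chars[tpl$idx34][tpl$idx10_in_34], collapse = "")
  sig <- extract_signature(tpl$anchor_sequence)
  expect_identical(sig$signature_34, own34)
  expect_identical(sig$signature_10, own10)
  expect_equal(sig$coverage, 1)

  # a 5-aa insertion away from the active-site positions leaves both
  # signatures unchanged
  ins_at <- 50L
  with_ins <- paste0(substr(tpl$anchor_sequence, 1, ins_at), "WWWWW",
                     substr(tpl$anchor_sequence, ins_at + 1,
                            nchar(tpl$anchor_sequence)))
  sig_ins <- extract_signature(with_ins)
  expect_identical(sig_ins$signature_34, own34)
  expect_identical(sig_ins$signature_10, own10)

  expect_error(extract_signature("MKLV"), "too short")
})

test_that("the 10-residue code is the indexed subset of the 34-residue signature", {
  tpl <- signature_template()
  expect_true(all(diff(tpl$idx10_in_34) > 0))
  expect_true(all(tpl$idx10_in_34 >= 1 & tpl$idx10_in_34 <= 34))
  panel <- tt_panel()
  arefs <- panel[panel$kind == "A", ]
  for (i in seq_len(nrow(arefs))) {
    s34 <- strsplit(arefs$signature_34[i], "")[[1]]
    expect_identical(paste0(s34[tpl$idx10_in_34], collapse = ""),
                     arefs$signature_10[i])
  }
})

test_that("nearest-neighbour substrate calls behave at the extremes", {
  panel <- tt_panel()
  leu_sig <- panel$signature_10[panel$kind == "A" & panel$label == "Leu"][1]
  call <- call_substrate_nn(leu_sig, panel)
  expect_identical(call$label, "Leu")
  expect_identical(call$score, 10)
  expect_identical(call$confidence, "confident")

  # an all-different signature scores below the floor
  flip <- chartr("ACDEFGHIKLMNPQRSTVWY", "CDEFGHIKLMNPQRSTVWYA",
                 panel$signature_10[panel$kind == "A"][1])
  worst <- call_substrate_nn(flip, panel)
  expect_identical(worst$confidence, "none")
})

test_that("constructed NN ties are reported in full, ordered by reference id", {
  refs <- reference_panel(
    id = c("Ile-r1", "Leu-r1", "Val-r1"),
    kind = "A", label = c("Ile", "Leu", "Val"),
    sequence = strrep("A", 300),
    signature_34 = strrep("A", 34),
    signature_10 = c("DAFFLGMVFY", "DAFFLGMVWC", "WWWWWWWWWW"))
  # query at 8/10 from both the Ile and the Leu reference
  call <- call_substrate_nn("DAFFLGMVYA", refs)
  expect_identical(call$score, 8)
  expect_identical(call$confidence, "ambiguous")
  expect_identical(call$ties, c("Ile", "Leu"))
})

test_that("NN calls are invariant to panel ordering", {
  panel <- tt_panel()
  set.seed(42)
  q <- panel$signature_10[panel$kind == "A" & panel$label == "Gln"][2]
  base <- call_substrate_nn(q, panel)
  for (i in 1:5) {
    shuffled <- panel[sample.int(nrow(panel)), ]
    again <- call_substrate_nn(q, shuffled)
    expect_identical(again$label, base$label)
    expect_identical(again$score, base$score)
    expect_identical(again$ties, base$ties)
  }
})

test_that("mutating a position matched by the top reference never raises its score", {
  panel <- tt_panel()
  top <- panel[panel$kind == "A", ][1, ]
  q <- top$signature_10
  s0 <- call_substrate_nn(q, panel)$score
  qs <- strsplit(q, "")[[1]]
  for (pos in 1:10) {
    mut <- qs
    mut[pos] <- if (qs[pos] == "A") "C" else "A"
    s1 <- sum(strsplit(top$signature_10, "")[[1]] == mut)
    expect_lte(s1, s0)
  }
})

test_that("placement calls a copied reference at near-zero patristic distance", {
  panel <- tt_panel()
  ser1 <- panel[panel$kind == "A" & panel$label == "Ser", ][1, ]
  call <- call_substrate_placement(ser1$sequence, panel, domain_id = "q")
  expect_identical(call$label, "Ser")
  expect_lt(call$score, 0.05)
})

test_that("placement with an imported newick tree matches the internal tree", {
  panel <- tt_panel()
  arefs <- prepare_panel(panel[panel$kind == "A", ])
  set.seed(7)
  q <- mutate_sequence(arefs$sequence[5], 0.08)
  internal <- call_substrate_placement(q, arefs, domain_id = "q")
  # rebuild the same tree externally, write, re-import
  prof <- domain_profiles()
  qproj <- as.character(nrpsmith:::.project_to_template(q, prof$A$template))
  rows <- c(stats::setNames(qproj, "q"),
            stats::setNames(arefs$proj, arefs$id))
  tr <- nj_tree(pairwise_distances(multiple_alignment(rows), "poisson"))
  path <- withr::local_tempfile(fileext = ".nwk")
  write_tree_newick(tr, path)
  imported <- call_substrate_placement(q, arefs,
                                       tree = read_tree_newick(path),
                                       domain_id = "q")
  expect_identical(imported$label, internal$label)
  expect_equal(imported$score, internal$score, tolerance = 1e-6)
})

test_that("C-domain typing recognizes each planted subtype", {
  panel <- tt_panel()
  prof <- domain_profiles()
  set.seed(11)
  for (sub in c("starter", "C/E", "conventional")) {
    q <- mutate_sequence(prof$C$subtypes[[sub]], 0.10)
    res <- classify_c_domain(q, panel, position_in_line = 3)
    expect_identical(res$class, sub)
    expect_false(res$starter_candidate)
  }
  res1 <- classify_c_domain(prof$C$subtypes$starter, panel, 1)
  expect_true(res1$starter_candidate)
  expect_error(classify_c_domain("MK", panel, 1), "too short")
  no_starter <- panel[!(panel$kind == "C" & panel$label == "starter"), ]
  expect_error(classify_c_domain(prof$C$subtypes$starter, no_starter, 1),
               "all three classes")
})

test_that("TE typing reports ordinal agreement and flags conflicts", {
  panel <- tt_panel()
  prof <- domain_profiles()
  set.seed(12)
  te2q <- mutate_sequence(prof$TE$subtypes$TE2, 0.10)
  agree <- classify_te(te2q, panel, ordinal_in_tandem = 2)
  expect_identical(agree$class, "TE2")
  expect_true(agree$ordinal_agrees)
  conflict <- classify_te(te2q, panel, ordinal_in_tandem = 1)
  expect_identical(conflict$class, "TE2")
  expect_false(conflict$ordinal_agrees)
  expect_true(is.na(classify_te(te2q, panel)$ordinal_agrees))
  expect_error(classify_te(te2q, panel[panel$kind != "TE", ], 1), "TE1 and TE2")
})

test_that("asymmetric divergence shows up as tighter intra-class patristic spread", {
  # TE1 references evolved at a higher rate than TE2: mean intra-class
  # patristic distance must rank accordingly
  prof <- domain_profiles()
  set.seed(13)
  seqs <- c(
    stats::setNames(lapply(1:5, function(i) {
      mutate_sequence(prof$TE$subtypes$TE1, 0.15)
    }), paste0("TE1-", 1:5)),
    stats::setNames(lapply(1:5, function(i) {
      mutate_sequence(prof$TE$subtypes$TE2, 0.04)
    }), paste0("TE2-", 1:5)))
  rows <- vapply(seqs, function(s) {
    as.character(nrpsmith:::.project_to_template(s, prof$TE$template))
  }, character(1))
  pd <- patristic_distances(nj_tree(pairwise_distances(
    multiple_alignment(rows), "poisson")))
  intra <- function(prefix) {
    ids <- grep(prefix, rownames(pd), value = TRUE)
    mean(pd[ids, ids][upper.tri(diag(length(ids)))])
  }
  expect_lt(intra("TE2"), intra("TE1"))
})
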