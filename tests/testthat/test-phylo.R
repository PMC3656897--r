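test_that("p-distances count mismatches over gap-free columns", {
  expect_identical(pairwise_distances(c(a = "AAAA", b = "AAAA"))["a", "b"], 0)
  expect_identical(pairwise_distances(c(a = "AAAA", b = "AAAT"))["a", "b"], 0.25)
  # gapped columns are excluded pair-wise
  d <- pairwise_distances(c(a = "A-CD", b = "AAC-", c = "AACD"))
  expect_identical(d["a", "b"], 0)   # only columns 1 and 3 comparable
  expect_error(pairwise_distances(c(a = "A---", b = "-AAA")), "comparable")
  # Poisson correction and saturation guard
  dp <- pairwise_distances(c(a = "AAAA", b = "AAAT"), model = "poisson")
  expect_equal(dp["a", "b"], -log(1 - 0.25))
  expect_error(pairwise_distances(c(a = "AAAA", b = "TTTT"),
                                  model = "poisson"), "saturated")
})

test_that("p-distances agree with a brute-force per-column recount", {
  set.seed(301)
  aa <- c(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], "-")
  for (rep in 1:20) {
    rows <- vapply(1:4, function(i) {
      paste0(sample(aa, 60, TRUE, prob = c(rep(1, 20), 3)), collapse = "")
    }, character(1))
    names(rows) <- paste0("s", 1:4)
    d <- try(pairwise_distances(rows), silent = TRUE)
    if (inherits(d, "try-error")) next  # no comparable columns: guarded above
    m <- do.call(rbind, strsplit(rows, ""))
    for (i in 1:3) for (j in (i + 1):4) {
      ok <- m[i, ] != "-" & m[j, ] != "-"
      expect_equal(d[i, j], sum(m[i, ok] != m[j, ok]) / sum(ok))
    }
  }
})

test_that("three-taxon NJ reproduces the closed-form branch lengths", {
  d <- matrix(c(0, 3, 5, 3, 0, 6, 5, 6, 0), 3, 3,
              dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  tr <- nj_tree(d)
  pd <- patristic_distances(tr)
  expect_equal(pd[rownames(d), colnames(d)], d, tolerance = 1e-9)
  # closed form: pendant branch of a = (dab + dac - dbc) / 2 = 1
  br <- tr$edge.length[tr$edge[, 2] == match("a", tr$tip.label)]
  expect_equal(br, 1)
  expect_error(nj_tree(d[1:2, 1:2]), ">= 3")
})

test_that("NJ recovers additive four-taxon trees exactly", {
  # additive matrix from quartet ((a,b),(c,d)) with internal branch 1
  d <- matrix(0, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  d["a", "b"] <- 3; d["a", "c"] <- 5; d["a", "d"] <- 3
  d["b", "c"] <- 6; d["b", "d"] <- 4; d["c", "d"] <- 4
  d <- d + t(d)
  tr <- nj_tree(d)
  expect_equal(patristic_distances(tr)[rownames(d), colnames(d)], d,
               tolerance = 1e-9)
  expect_true(all(tr$edge.length >= 0))
  # equal distances: valid tree, non-negative branches, additive fit
  deq <- matrix(1, 4, 4, dimnames = dimnames(d)); diag(deq) <- 0
  treq <- nj_tree(deq)
  expect_true(all(treq$edge.length >= 0))
  expect_equal(patristic_distances(treq)[rownames(deq), colnames(deq)], deq,
               tolerance = 1e-9)
})

test_that("patristic distances equal the graph-path oracle on random trees", {
  set.seed(302)
  for (i in 1:20) {
    tr <- ape::rtree(sample(4:15, 1))
    expect_equal(patristic_distances(tr), graph_path_patristic(tr),
                 tolerance = 1e-10)
  }
  cherry <- ape::read.tree(text = "(x:0.1,y:0.2);")
  expect_equal(patristic_distances(cherry)["x", "y"], 0.3)
  expect_identical(diag(patristic_distances(cherry)), c(x = 0, y = 0))
})

test_that("patristic grouping closes transitively and exposes raw pairs", {
  d <- matrix(c(0, 0.3, 0.6, 0.3, 0, 0.3, 0.6, 0.3, 0), 3, 3,
              dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  groups <- group_by_patristic(d, 0.45)
  expect_length(groups, 1)
  expect_identical(groups[["a"]], c("a", "b", "c"))
  pairs <- group_by_patristic(d, 0.45, closure = "pairs")
  expect_identical(nrow(pairs), 2L)   # a-b and b-c only, a-c is 0.6
  # all pairs at/above threshold: singletons
  dd <- d; dd[dd > 0] <- 0.5
  expect_length(group_by_patristic(dd, 0.45), 3)
  expect_error(group_by_patristic(d, -1), "threshold")
})

test_that("outgroup rooting preserves patristic distances and leaves", {
  set.seed(303)
  tr <- ape::rtree(8)
  rooted <- root_with_outgroup(tr, "t3")
  expect_true(ape::is.rooted(rooted))
  expect_setequal(rooted$tip.label, tr$tip.label)
  expect_equal(patristic_distances(rooted), patristic_distances(tr),
               tolerance = 1e-10)
  expect_error(root_with_outgroup(tr, "no_such_leaf"), "not in tree")
  tr3 <- nj_tree(matrix(c(0, 1, 2, 1, 0, 3, 2, 3, 0), 3, 3,
                        dimnames = list(c("a", "b", "c"), c("a", "b", "c"))))
  r3 <- root_with_outgroup(tr3, "c")
  expect_identical(sum(r3$edge[, 1] == (length(r3$tip.label) + 1L)), 2L)
})

test_that("newick round trips preserve topology, labels and branch lengths", {
  set.seed(304)
  for (i in 1:10) {
    tr <- ape::rtree(sample(4:12, 1))
    path <- withr::local_tempfile(fileext = ".nwk")
    write_tree_newick(tr, path)
    back <- read_tree_newick(path)
    expect_identical(sort(back$tip.label), sort(tr$tip.label))
    expect_equal(patristic_distances(back), patristic_distances(tr),
                 tolerance = 1e-9)
  }
})

test_that("distance matrices round-trip through TSV", {
  d <- patristic_distances(ape::rtree(5))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_distance_tsv(d, path)
  expect_equal(read_distance_tsv(path), d, tolerance = 1e-12)
})
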