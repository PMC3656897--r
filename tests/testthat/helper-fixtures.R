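# Shared, lazily built fixtures. Heavy objects (reference panel with
# projections, a simulated assembly line) are built once per test run.

.tt_cache <- new.env()

# independent oracle: patristic distances as shortest paths on the edge graph
graph_path_patristic <- function(tree) {
  n_tip <- length(tree$tip.label)
  g <- igraph::graph_from_data_frame(
    data.frame(from = tree$edge[, 1], to = tree$edge[, 2]),
    directed = FALSE)
  d <- igraph::distances(g, weights = tree$edge.length)
  ids <- as.integer(igraph::V(g)$name)
  tips <- match(seq_len(n_tip), ids)
  out <- d[tips, tips]
  dimnames(out) <- list(tree$tip.label, tree$tip.label)
  ord <- sort(tree$tip.label)
  out[ord, ord]
}

tt_config <- function() {
  if (is.null(.tt_cache$config)) .tt_cache$config <- sim_config(seed = 101L)
  .tt_cache$config
}

tt_panel <- function() {
  if (is.null(.tt_cache$panel)) {
    .tt_cache$panel <- prepare_panel(make_reference_panel(tt_config()))
  }
  .tt_cache$panel
}

tt_sim <- function() {
  if (is.null(.tt_cache$sim)) {
    .tt_cache$sim <- simulate_assembly_line(tt_config())
  }
  .tt_cache$sim
}

tt_extdata <- function(name) {
  system.file("extdata", name, package = "nrpsmith")
}

# xantholysin A as printed: peptide, 3-hydroxydecanoate, Ser7 lactone
tt_xanA <- function() {
  lipopeptide_structure(
    c("Leu", "Glu", "Gln", "Val", "Leu", "Gln", "Ser",
      "Val", "Leu", "Gln", "Leu", "Leu", "Gln", "Ile"),
    fatty_acid = fatty_acid_spec(10),
    lactone_donor = 7)
}

# random peptide over the proteinogenic registry with a Ser planted so a
# lactone is always constructible
tt_random_structure <- function(n, acylated = TRUE, cyclic = TRUE) {
  res <- sample(known_residues(include_ambiguous = FALSE), n, replace = TRUE)
  ser_at <- sample(seq_len(max(n - 1, 1)), 1)
  res[ser_at] <- "Ser"
  lipopeptide_structure(
    res,
    fatty_acid = if (acylated) fatty_acid_spec(sample(6:14, 1)) else NULL,
    lactone_donor = if (cyclic) ser_at else NULL)
}
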