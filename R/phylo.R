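#' Multiple alignment container
#'
#' A minimal aligned-sequence container: a named character vector of
#' equal-length rows over the amino-acid alphabet plus the gap character `-`.
#'
#' @param rows Named character vector (>= 2 rows, unique labels).
#' @return Named character vector of class `msa_rows`.
#' @export
multiple_alignment <- function(rows) {
  stopifnot(length(rows) >= 2)
  if (is.null(names(rows)) || anyDuplicated(names(rows))) {
    stop("alignment rows need unique labels", call. = FALSE)
  }
  if (length(unique(nchar(rows))) != 1) {
    stop("alignment rows must have equal length", call. = FALSE)
  }
  structure(toupper(rows), class = "msa_rows")
}

#' Pairwise distances from an alignment
#'
#' p-distances are computed over columns where neither row has a gap;
#' the Poisson correction `-ln(1 - p)` is optional. A pair with zero
#' comparable columns, or a saturated pair (`p >= 1` under correction),
#' is an error naming the pair.
#'
#' @param aln A [multiple_alignment()] (or named character vector).
#' @param model `"p-distance"` or `"poisson"`.
#' @return Symmetric distance matrix with zero diagonal, labelled by row.
#' @export
pairwise_distances <- function(aln, model = c("p-distance", "poisson")) {
  model <- match.arg(model)
  if (!inherits(aln, "msa_rows")) aln <- multiple_alignment(aln)
  labs <- names(aln)
  n <- length(aln)
  mat <- do.call(rbind, strsplit(unclass(aln), ""))
  d <- matrix(0, n, n, dimnames = list(labs, labs))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      ok <- mat[i, ] != "-" & mat[j, ] != "-"
      if (!any(ok)) {
        stop("no comparable columns between '", labs[i], "' and '", labs[j],
             "'", call. = FALSE)
      }
      p <- mean(mat[i, ok] != mat[j, ok])
      if (model == "poisson") {
        if (p >= 1) {
          stop("saturated pair under Poisson correction: '", labs[i],
               "' vs '", labs[j], "'", call. = FALSE)
        }
        p <- -log(1 - p)
      }
      d[i, j] <- d[j, i] <- p
    }
  }
  d
}

.check_dist <- function(d) {
  stopifnot(is.matrix(d), nrow(d) == ncol(d))
  if (is.null(rownames(d))) stop("distance matrix needs labels", call. = FALSE)
  if (any(!is.finite(d))) stop("distances must be finite", call. = FALSE)
  if (any(abs(d - t(d)) > 1e-12) || any(diag(d) != 0)) {
    stop("distance matrix must be symmetric with zero diagonal", call. = FALSE)
  }
  invisible(d)
}

#' Neighbor-joining tree
#'
#' Saitou-Nei neighbor joining with two deterministic refinements: ties in
#' the Q matrix are broken by the lexicographically smallest label pair, and
#' a negative intermediate branch length is clamped to zero with the deficit
#' shifted to its sister branch (so the path length between the joined pair
#' is preserved and all branch lengths are non-negative).
#'
#' @param d Symmetric labelled distance matrix (>= 3 labels).
#' @return An unrooted `ape::phylo` tree.
#' @export
nj_tree <- function(d) {
  .check_dist(d)
  n <- nrow(d)
  if (n < 3) stop("neighbor joining needs >= 3 labels", call. = FALSE)
  labs <- rownames(d)
  # newick-safe working labels; originals restored on the parsed tree
  safe <- gsub("[]['\"(),:;[:space:]]", "_", labs)
  if (anyDuplicated(safe)) {
    safe <- paste0(safe, "_", seq_along(safe))
  }
  # active nodes represented by newick subtree strings; grow by joining
  sub <- stats::setNames(safe, labs)
  act <- labs
  D <- d
  while (length(act) > 2) {
    m <- length(act)
    r <- rowSums(D)
    Q <- (m - 2) * D - outer(r, r, `+`)
    diag(Q) <- Inf
    qmin <- min(Q)
    cand <- which(Q <= qmin + 1e-12, arr.ind = TRUE)
    cand <- cand[cand[, 1] < cand[, 2], , drop = FALSE]
    pair_lab <- cbind(act[cand[, 1]], act[cand[, 2]])
    pair_lab <- t(apply(pair_lab, 1, sort))
    ord <- order(pair_lab[, 1], pair_lab[, 2])
    i <- cand[ord[1], 1]; j <- cand[ord[1], 2]
    vi <- D[i, j] / 2 + (r[i] - r[j]) / (2 * (m - 2))
    vj <- D[i, j] - vi
    # clamp negatives, shifting the deficit to the sister branch
    if (vi < 0) { vj <- vj + vi; vi <- 0 }
    if (vj < 0) { vi <- vi + vj; vj <- 0 }
    new_lab <- paste0("(", act[i], "|", act[j], ")")
    new_sub <- sprintf("(%s:%.12g,%s:%.12g)", sub[[act[i]]], vi,
                       sub[[act[j]]], vj)
    dk <- (D[i, ] + D[j, ] - D[i, j]) / 2
    keep <- setdiff(seq_len(m), c(i, j))
    D2 <- matrix(0, length(keep) + 1, length(keep) + 1)
    D2[seq_along(keep), seq_along(keep)] <- D[keep, keep, drop = FALSE]
    D2[length(keep) + 1, seq_along(keep)] <- dk[keep]
    D2[seq_along(keep), length(keep) + 1] <- dk[keep]
    act2 <- c(act[keep], new_lab)
    dimnames(D2) <- list(act2, act2)
    sub <- c(sub[act[keep]], stats::setNames(new_sub, new_lab))
    act <- act2
    D <- D2
  }
  v <- max(D[1, 2], 0)
  nwk <- sprintf("(%s:%.12g,%s:%.12g);", sub[[act[1]]], v / 2,
                 sub[[act[2]]], v / 2)
  tree <- ape::read.tree(text = nwk)
  tree$tip.label <- labs[match(tree$tip.label, safe)]
  # collapse the degree-2 node introduced by the final join: output unrooted
  ape::unroot(tree)
}

#' Patristic distances of a tree
#'
#' Leaf-to-leaf distances as summed branch lengths along the unique
#' connecting path.
#'
#' @param tree An `ape::phylo` with branch lengths.
#' @return Labelled symmetric matrix ordered by tip label.
#' @export
patristic_distances <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  if (is.null(tree$edge.length)) {
    stop("tree has no branch lengths", call. = FALSE)
  }
  d <- stats::cophenetic(tree)
  ord <- sort(rownames(d))
  d[ord, ord]
}

#' Group leaves by a patristic-distance threshold
#'
#' The grouping rule colours two leaves alike when their patristic distance
#' is below `threshold`. With `closure = "components"` (default) the relation
#' is closed transitively: groups are the connected components of the graph
#' with an edge for every pair below threshold (single linkage). With
#' `closure = "pairs"` the raw sub-threshold pairs are returned instead.
#'
#' @param d Labelled patristic distance matrix.
#' @param threshold Positive distance threshold (default 0.45).
#' @param closure `"components"` or `"pairs"`.
#' @return For `"components"`: a list of character vectors (groups), ordered
#'   and labelled by their lexicographically smallest member; singletons
#'   included. For `"pairs"`: a data.frame `a`, `b`, `distance`.
#' @export
group_by_patristic <- function(d, threshold = 0.45,
                               closure = c("components", "pairs")) {
  closure <- match.arg(closure)
  .check_dist(d)
  stopifnot(threshold > 0)
  labs <- rownames(d)
  adj <- d < threshold
  diag(adj) <- FALSE
  if (closure == "pairs") {
    idx <- which(adj & upper.tri(adj), arr.ind = TRUE)
    out <- data.frame(a = labs[idx[, 1]], b = labs[idx[, 2]],
                      distance = d[idx], stringsAsFactors = FALSE)
    return(out[order(out$a, out$b), , drop = FALSE])
  }
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  comp <- igraph::components(g)$membership
  groups <- split(labs, comp)
  groups <- lapply(groups, sort)
  groups <- groups[order(vapply(groups, `[`, "", 1))]
  names(groups) <- vapply(groups, `[`, "", 1)
  groups
}

#' Root a tree on an outgroup leaf
#'
#' Inserts the root at the midpoint of the outgroup's pendant edge, which
#' leaves all leaf-to-leaf patristic distances unchanged.
#'
#' @param tree An `ape::phylo`.
#' @param leaf_label Outgroup tip label (must be present).
#' @return A rooted `ape::phylo`.
#' @export
root_with_outgroup <- function(tree, leaf_label) {
  stopifnot(inherits(tree, "phylo"))
  tip <- match(leaf_label, tree$tip.label)
  if (is.na(tip)) {
    stop("outgroup label '", leaf_label, "' not in tree", call. = FALSE)
  }
  edge_row <- which(tree$edge[, 2] == tip)
  rooted <- phytools::reroot(tree, tip,
                             position = tree$edge.length[edge_row] / 2)
  rooted
}

#' Read / write newick trees
#'
#' Thin wrappers over ape's newick reader/writer, provided so externally
#' built trees (e.g. maximum-likelihood trees) can be imported as the
#' fidelity path for placement and patristic grouping.
#'
#' @param path File path.
#' @param tree An `ape::phylo`.
#' @return `read_tree_newick()`: an `ape::phylo`.
#' @export
read_tree_newick <- function(path) {
  tree <- ape::read.tree(path)
  if (is.null(tree)) stop("cannot parse newick in ", path, call. = FALSE)
  tree
}

#' @rdname read_tree_newick
#' @export
write_tree_newick <- function(tree, path) {
  ape::write.tree(tree, file = path, digits = 12)
  invisible(path)
}

#' Write / read a labelled distance matrix as TSV
#'
#' @param d Labelled symmetric matrix.
#' @param path File path.
#' @return `read_distance_tsv()`: the matrix.
#' @export
write_distance_tsv <- function(d, path) {
  .check_dist(d)
  utils::write.table(cbind(label = rownames(d), as.data.frame(d)), path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_distance_tsv
#' @export
read_distance_tsv <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  labs <- tab[[1]]
  m <- as.matrix(tab[, -1, drop = FALSE])
  rownames(m) <- labs
  storage.mode(m) <- "double"
  .check_dist(m)
  m
}
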