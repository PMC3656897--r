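# Alignment constants for signature extraction and template projection,
# fixed for bit-exact reproducibility.
.aln_config <- list(matrix = "BLOSUM62", gap_open = 11, gap_extend = 1)

.subst_matrix <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      e <- new.env()
      utils::data(list = .aln_config$matrix, package = "Biostrings", envir = e)
      cache <<- get(.aln_config$matrix, envir = e)
    }
    cache
  }
})

# Globally align `query` to `template` and report, for every template
# position, the query residue aligned to it ('-' where the query is gapped).
.project_to_template <- function(query, template) {
  mat <- .subst_matrix()
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(query), Biostrings::AAString(template),
    substitutionMatrix = mat, gapOpening = .aln_config$gap_open,
    gapExtension = .aln_config$gap_extend, type = "global")
  p <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1]]
  s <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1]]
  out <- character(nchar(template))
  pos <- 0L
  for (k in seq_along(s)) {
    if (s[k] != "-") {
      pos <- pos + 1L
      out[pos] <- p[k]
    }
  }
  proj <- paste0(out, collapse = "")
  attr(proj, "coverage") <- mean(out != "-")
  proj
}

#' Build a reference domain panel
#'
#' @param id,kind,label,sequence Parallel vectors describing each reference
#'   domain: `kind` in C/A/TE; `label` the class (A: substrate 3-letter code,
#'   possibly non-proteinogenic or Xle; C: `starter`/`C/E`/`conventional`;
#'   TE: `TE1`/`TE2`).
#' @param signature_34,signature_10 For A references: active-site signature
#'   strings (lengths 34 and 10), `NA` otherwise.
#' @return data.frame of class `reference_panel`.
#' @export
reference_panel <- function(id, kind, label, sequence,
                            signature_34 = NA, signature_10 = NA) {
  stopifnot(!anyDuplicated(id), all(kind %in% c("A", "C", "TE")))
  ok_label <- ifelse(
    kind == "C", label %in% c("starter", "C/E", "conventional"),
    ifelse(kind == "TE", label %in% c("TE1", "TE2"), TRUE))
  if (!all(ok_label)) {
    stop("illegal label(s) for kind: ",
         paste(unique(label[!ok_label]), collapse = ", "), call. = FALSE)
  }
  s34 <- rep_len(as.character(signature_34), length(id))
  s10 <- rep_len(as.character(signature_10), length(id))
  bad34 <- kind == "A" & !is.na(s34) & nchar(s34) != 34
  bad10 <- kind == "A" & !is.na(s10) & nchar(s10) != 10
  if (any(bad34) || any(bad10)) {
    stop("A-domain signatures must have lengths 34 and 10", call. = FALSE)
  }
  structure(data.frame(id = id, kind = kind, label = label,
                       sequence = toupper(sequence),
                       signature_34 = toupper(s34), signature_10 = toupper(s10),
                       stringsAsFactors = FALSE),
            class = c("reference_panel", "data.frame"))
}

#' Precompute template projections for a panel
#'
#' Projects each reference sequence onto its kind's scaffold once, so that
#' repeated placement calls against the same panel do not realign the
#' references. Idempotent.
#'
#' @param refs A [reference_panel()].
#' @param profiles Domain profiles, see [domain_profiles()].
#' @return The panel with a `proj` column added.
#' @export
prepare_panel <- function(refs, profiles = domain_profiles()) {
  if (!is.null(refs$proj)) return(refs)
  refs$proj <- vapply(seq_len(nrow(refs)), function(i) {
    as.character(.project_to_template(refs$sequence[i],
                                      profiles[[refs$kind[i]]]$template))
  }, character(1))
  refs
}

#' Extract the 34/10 active-site signature of an A domain
#'
#' The A domain is globally aligned to the packaged anchor scaffold
#' (BLOSUM62, affine gaps open 11 / extend 1); the residues aligned to the
#' 34 template positions form the full signature, and the 10 diagnostic
#' positions (indices into the 34) form the substrate-pocket code used for
#' nearest-neighbour prediction.
#'
#' @param a_domain_sequence A-domain amino-acid sequence (>= 200 residues).
#' @param template A [signature_template()].
#' @return list with `signature_34`, `signature_10` and `coverage` (fraction
#'   of template positions covered by aligned query residues).
#' @export
extract_signature <- function(a_domain_sequence,
                              template = signature_template()) {
  if (nchar(a_domain_sequence) < 200) {
    stop("A-domain sequence too short (< 200 aa)", call. = FALSE)
  }
  proj <- .project_to_template(a_domain_sequence, template$anchor_sequence)
  if (attr(proj, "coverage") < 0.6) {
    stop("signature not extractable: alignment covers < 60% of the template",
         call. = FALSE)
  }
  chars <- strsplit(as.character(proj), "")[[1]]
  s34 <- paste0(chars[template$idx34], collapse = "")
  s10 <- paste0(chars[template$idx34][template$idx10_in_34], collapse = "")
  list(signature_34 = s34, signature_10 = s10,
       coverage = attr(proj, "coverage"))
}

.specificity_call <- function(domain_id, label, method, score, ties,
                              confidence) {
  structure(list(domain_id = domain_id, label = label, method = method,
                 score = score, ties = ties, confidence = confidence),
            class = "specificity_call")
}

#' @export
print.specificity_call <- function(x, ...) {
  cat("<call> ", x$domain_id, ": ", x$label, " (", x$method, ", score ",
      format(x$score, digits = 4), ", ", x$confidence,
      if (length(x$ties) > 1) paste0(", ties: ",
                                     paste(x$ties, collapse = "/")) else "",
      ")\n", sep = "")
  invisible(x)
}

#' Substrate call by signature nearest neighbour
#'
#' Scores the query's 10-residue pocket code against every A reference by
#' exact identities out of 10 and predicts the label of the best match.
#' Co-optimal references with different labels make the call ambiguous; a
#' best score below `floor` makes it `none`.
#'
#' @param signature_10 Query 10-residue signature (string).
#' @param references A [reference_panel()] (A rows are used).
#' @param floor Confidence floor (identities out of 10; default 6).
#' @param domain_id Identifier carried into the call.
#' @return A `specificity_call`: label, `method = "signature-NN"`, score
#'   (identities out of 10), ties (labels at the maximum, ordered by
#'   reference id) and a confidence flag.
#' @export
call_substrate_nn <- function(signature_10, references, floor = 6,
                              domain_id = "query") {
  refs <- references[references$kind == "A" & !is.na(references$signature_10), ,
                     drop = FALSE]
  if (nrow(refs) == 0) stop("no A references with signatures", call. = FALSE)
  refs <- refs[order(refs$id), , drop = FALSE]
  q <- strsplit(toupper(signature_10), "")[[1]]
  stopifnot(length(q) == 10)
  scores <- vapply(refs$signature_10, function(s) {
    sum(strsplit(s, "")[[1]] == q)
  }, numeric(1), USE.NAMES = FALSE)
  best <- max(scores)
  top_labels <- unique(refs$label[scores == best])  # ordered by reference id
  label <- top_labels[1]
  confidence <- if (best < floor) "none"
                else if (length(top_labels) > 1) "ambiguous"
                else "confident"
  .specificity_call(domain_id, label, "signature-NN", best, top_labels,
                    confidence)
}

# shared placement machinery: project query + references onto the kind
# scaffold, build (or accept) a tree, and call the label of the reference
# nearest by patristic distance
.placement_call <- function(query_seq, refs, kind, domain_id,
                            tree = NULL, delta = 0.05, method = "placement",
                            profiles = domain_profiles()) {
  refs <- refs[refs$kind == kind, , drop = FALSE]
  if (nrow(refs) < 3) stop("placement needs >= 3 references", call. = FALSE)
  refs <- prepare_panel(refs, profiles)
  refs <- refs[order(refs$id), , drop = FALSE]
  if (is.null(tree)) {
    qproj <- as.character(.project_to_template(
      query_seq, profiles[[kind]]$template))
    rows <- c(stats::setNames(list(qproj), domain_id),
              stats::setNames(as.list(refs$proj), refs$id))
    aln <- multiple_alignment(unlist(rows))
    d <- pairwise_distances(aln, model = "poisson")
    tree <- nj_tree(d)
  }
  if (!domain_id %in% tree$tip.label) {
    stop("query '", domain_id, "' not among tree tips", call. = FALSE)
  }
  pd <- patristic_distances(tree)
  to_refs <- pd[domain_id, intersect(colnames(pd), refs$id)]
  to_refs <- to_refs[order(names(to_refs))]
  best <- min(to_refs)
  label <- refs$label[match(names(to_refs)[which.min(to_refs)], refs$id)]
  near_labels <- unique(refs$label[match(
    names(to_refs)[to_refs <= best + delta], refs$id)])
  confidence <- if (length(near_labels) > 1) "ambiguous" else "confident"
  .specificity_call(domain_id, label, method, best,
                    near_labels, confidence)
}

#' Substrate call by phylogenetic placement
#'
#' Builds a neighbor-joining tree of the query plus the A-domain references
#' (Poisson-corrected distances on template-projected sequences), unless an
#' externally built tree containing the query tip is supplied, and predicts
#' the label of the reference with the smallest patristic distance to the
#' query. Two different labels within `delta` of the minimum make the call
#' ambiguous.
#'
#' @param a_domain_sequence Query A-domain sequence.
#' @param references A [reference_panel()].
#' @param tree Optional imported `ape::phylo` whose tips include `domain_id`
#'   and the reference ids.
#' @param delta Ambiguity margin on patristic distance (default 0.05).
#' @param domain_id Identifier carried into the call (and expected tip name).
#' @return A `specificity_call` with `method = "placement"` and the patristic
#'   distance as score.
#' @export
call_substrate_placement <- function(a_domain_sequence, references,
                                     tree = NULL, delta = 0.05,
                                     domain_id = "query") {
  .placement_call(a_domain_sequence, references, "A", domain_id,
                  tree = tree, delta = delta)
}

#' Classify a condensation domain
#'
#' Nearest reference class (starter / dual C\\/E / conventional) by the same
#' patristic-placement machinery as substrate calling. A module-1 C domain is
#' additionally annotated as positional starter candidate; class call and
#' evidence are both reported.
#'
#' @param c_domain_sequence C-domain sequence (>= 200 aa).
#' @param references A [reference_panel()] containing all three C classes.
#' @param position_in_line Module index of the domain (1-based).
#' @param tree,delta As in [call_substrate_placement()].
#' @param domain_id Identifier.
#' @return list with `class`, `starter_candidate` (positional), `evidence`
#'   (the placement `specificity_call`).
#' @export
classify_c_domain <- function(c_domain_sequence, references, position_in_line,
                              tree = NULL, delta = 0.05,
                              domain_id = "query") {
  if (nchar(c_domain_sequence) < 200) {
    stop("C-domain sequence too short (< 200 aa)", call. = FALSE)
  }
  crefs <- references[references$kind == "C", , drop = FALSE]
  if (!all(c("starter", "C/E", "conventional") %in% crefs$label)) {
    stop("C references must contain all three classes", call. = FALSE)
  }
  call <- .placement_call(c_domain_sequence, references, "C", domain_id,
                          tree = tree, delta = delta)
  list(class = call$label,
       starter_candidate = identical(as.integer(position_in_line), 1L),
       evidence = call)
}

#' Classify a thioesterase domain
#'
#' Nearest-class call (TE1, the releasing/cyclizing domain, vs TE2, the
#' editing domain) with the tandem ordinal reported alongside; a
#' disagreement between the sequence-based call and the ordinal expectation
#' (first = TE1, second = TE2) is flagged, never silently resolved.
#'
#' @param te_sequence TE-domain sequence.
#' @param references A [reference_panel()] containing both TE classes.
#' @param ordinal_in_tandem 1 (first) or 2 (second), or `NA` if unknown.
#' @param tree,delta As in [call_substrate_placement()].
#' @param domain_id Identifier.
#' @return list with `class`, `ordinal`, `ordinal_agrees` (logical, `NA` if
#'   no ordinal given) and `evidence`.
#' @export
classify_te <- function(te_sequence, references, ordinal_in_tandem = NA,
                        tree = NULL, delta = 0.05, domain_id = "query") {
  terefs <- references[references$kind == "TE", , drop = FALSE]
  if (!all(c("TE1", "TE2") %in% terefs$label)) {
    stop("TE references must contain both TE1 and TE2", call. = FALSE)
  }
  call <- .placement_call(te_sequence, references, "TE", domain_id,
                          tree = tree, delta = delta)
  expected <- if (is.na(ordinal_in_tandem)) NA_character_
              else paste0("TE", ordinal_in_tandem)
  list(class = call$label, ordinal = ordinal_in_tandem,
       ordinal_agrees = if (is.na(expected)) NA else
         identical(call$label, expected),
       evidence = call)
}

#' Read / write a reference panel (FASTA + TSV)
#'
#' The shipped panel format is a FASTA of domain sequences plus a TSV with
#' columns `id`, `kind`, `label`, `signature_34`, `signature_10`.
#'
#' @param fasta_path,tsv_path File paths.
#' @param refs A [reference_panel()].
#' @return `read_reference_panel()`: a [reference_panel()].
#' @export
read_reference_panel <- function(fasta_path, tsv_path) {
  seqs <- read_fasta(fasta_path)
  tab <- utils::read.delim(tsv_path, stringsAsFactors = FALSE)
  need <- c("id", "kind", "label")
  miss <- setdiff(need, names(tab))
  if (length(miss)) {
    stop("panel TSV lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  ids <- vapply(seqs, `[[`, "", "id")
  idx <- match(tab$id, ids)
  if (anyNA(idx)) {
    stop("panel TSV ids missing from FASTA: ",
         paste(tab$id[is.na(idx)], collapse = ", "), call. = FALSE)
  }
  reference_panel(tab$id, tab$kind, tab$label,
                  vapply(seqs[idx], `[[`, "", "sequence"),
                  signature_34 = if (is.null(tab$signature_34)) NA else tab$signature_34,
                  signature_10 = if (is.null(tab$signature_10)) NA else tab$signature_10)
}

#' @rdname read_reference_panel
#' @export
write_reference_panel <- function(refs, fasta_path, tsv_path) {
  recs <- lapply(seq_len(nrow(refs)), function(i) {
    protein_record(refs$id[i], refs$sequence[i])
  })
  write_fasta(recs, fasta_path)
  utils::write.table(
    refs[, c("id", "kind", "label", "signature_34", "signature_10")],
    tsv_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(fasta_path, tsv_path))
}
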