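#' Protein record constructor
#'
#' @param id Record identifier (non-empty, unique within a set).
#' @param sequence Uppercase amino-acid sequence (20-letter alphabet + X).
#' @return list of class `protein_record`.
#' @export
protein_record <- function(id, sequence) {
  stopifnot(is.character(id), nzchar(id), is.character(sequence))
  sequence <- toupper(sequence)
  if (!nzchar(sequence)) stop("empty sequence for '", id, "'", call. = FALSE)
  if (grepl("[^ACDEFGHIKLMNPQRSTVWYX]", sequence)) {
    stop("illegal characters in sequence '", id, "'", call. = FALSE)
  }
  structure(list(id = id, sequence = sequence), class = "protein_record")
}

# identity fraction between two equal-length strings
.str_identity <- function(a, b) {
  av <- strsplit(a, "")[[1]]
  bv <- strsplit(b, "")[[1]]
  mean(av == bv)
}

#' Scan a protein for NRPS core domains
#'
#' Motif-anchored detection: for each domain kind the packaged 24-residue
#' anchor (a fixed window around the kind's core motif, e.g. HHxxxDG for C
#' domains) is searched allowing mismatches, each anchor match is extended to
#' the nominal domain window, and the window is scored by identity against
#' the kind's template (the best-matching subtype variant for kinds with
#' subtypes). Overlapping hits are resolved by score, then leftmost start,
#' then kind order C < A < T < TE. Deterministic.
#'
#' @param protein A [protein_record()] (or plain sequence string).
#' @param profiles Packaged profiles, see [domain_profiles()].
#' @param min_score Minimum template-identity score to keep a hit.
#' @return data.frame with columns `kind`, `subtype` (always `"unassigned"`
#'   at scan time; typing is the classification stage's job), `start`, `end`
#'   (0-based half-open), `score`; sorted by `start`.
#' @export
scan_domains <- function(protein, profiles = domain_profiles(),
                         min_score = 0.3) {
  seqstr <- if (inherits(protein, "protein_record")) protein$sequence
            else toupper(protein)
  subject <- Biostrings::AAString(seqstr)
  n <- nchar(seqstr)
  hits <- list()
  for (p in profiles) {
    m <- Biostrings::matchPattern(p$anchor, subject,
                                  max.mismatch = p$max_mismatch)
    if (length(m) == 0) next
    for (i in seq_along(m)) {
      a_start <- Biostrings::start(m)[i]          # 1-based
      start0 <- a_start - p$anchor_offset          # 0-based domain start
      end0 <- start0 + p$length
      start0c <- max(start0, 0L)
      end0c <- min(end0, n)
      window <- substr(seqstr, start0c + 1L, end0c)
      templates <- if (is.null(p$subtypes)) list(p$template) else p$subtypes
      score <- max(vapply(templates, function(tpl) {
        tpl_sub <- substr(tpl, start0c - start0 + 1L,
                          start0c - start0 + nchar(window))
        .str_identity(window, tpl_sub)
      }, numeric(1)))
      hits[[length(hits) + 1L]] <- data.frame(
        kind = p$kind, subtype = "unassigned",
        start = start0c, end = end0c, score = score,
        stringsAsFactors = FALSE)
    }
  }
  if (length(hits) == 0) {
    return(data.frame(kind = character(0), subtype = character(0),
                      start = integer(0), end = integer(0),
                      score = numeric(0), stringsAsFactors = FALSE))
  }
  hits <- do.call(rbind, hits)
  hits <- hits[hits$score >= min_score, , drop = FALSE]
  if (nrow(hits) == 0) return(hits)
  # deterministic resolution order: score desc, start asc, kind order
  kind_rank <- match(hits$kind, c("C", "A", "T", "TE"))
  hits <- hits[order(-hits$score, hits$start, kind_rank), , drop = FALSE]
  keep <- logical(nrow(hits))
  occupied <- matrix(numeric(0), ncol = 2)
  for (i in seq_len(nrow(hits))) {
    s <- hits$start[i]; e <- hits$end[i]
    if (nrow(occupied) == 0 ||
        all(e <= occupied[, 1] | s >= occupied[, 2])) {
      keep[i] <- TRUE
      occupied <- rbind(occupied, c(s, e))
    }
  }
  hits <- hits[keep, , drop = FALSE]
  hits <- hits[order(hits$start), , drop = FALSE]
  rownames(hits) <- NULL
  hits
}

#' Assemble domain hits into modules
#'
#' Greedy left-to-right application of the module grammar `(C A T)+ (TE){0,2}`.
#' Hits that cannot be absorbed into a complete module are reported as
#' diagnostics, never silently dropped.
#'
#' @param hits data.frame as produced by [scan_domains()] (non-overlapping,
#'   sorted by start).
#' @return list with `modules` (list of data.frames, one C/A/T triplet each),
#'   `te_hits` (data.frame of trailing TE hits, 0-2 rows) and `diagnostics`
#'   (character vector; `"no modules"` when no complete module was found,
#'   plus one entry per orphan hit).
#' @export
build_modules <- function(hits) {
  stopifnot(is.data.frame(hits))
  if (nrow(hits) > 1 && any(diff(hits$start) < 0)) {
    stop("hits must be sorted by start", call. = FALSE)
  }
  modules <- list()
  orphans <- hits[0, , drop = FALSE]
  i <- 1L
  n <- nrow(hits)
  while (i <= n) {
    if (i + 2L <= n &&
        hits$kind[i] == "C" && hits$kind[i + 1L] == "A" &&
        hits$kind[i + 2L] == "T") {
      modules[[length(modules) + 1L]] <- hits[i:(i + 2L), , drop = FALSE]
      i <- i + 3L
    } else if (hits$kind[i] == "TE") {
      break
    } else {
      orphans <- rbind(orphans, hits[i, , drop = FALSE])
      i <- i + 1L
    }
  }
  te_hits <- hits[0, , drop = FALSE]
  while (i <= n && hits$kind[i] == "TE" && nrow(te_hits) < 2L) {
    te_hits <- rbind(te_hits, hits[i, , drop = FALSE])
    i <- i + 1L
  }
  if (i <= n) orphans <- rbind(orphans, hits[i:n, , drop = FALSE])
  diagnostics <- character(0)
  if (length(modules) == 0) diagnostics <- "no modules"
  if (nrow(orphans) > 0) {
    diagnostics <- c(diagnostics, sprintf(
      "orphan %s hit at [%d, %d) not absorbed into a module",
      orphans$kind, orphans$start, orphans$end))
  }
  list(modules = modules, te_hits = te_hits, diagnostics = diagnostics)
}

#' Assemble annotated proteins into a multi-protein NRPS assembly line
#'
#' Proteins must be supplied in biosynthetic (gene) order, which is
#' biological knowledge, not inferred. Modules are numbered continuously
#' across proteins; TE domains are only legal on the terminal protein.
#'
#' @param proteins List of [protein_record()] in biosynthetic order.
#' @param annotations Optional list of [build_modules()] results parallel to
#'   `proteins`; computed by [scan_domains()] + [build_modules()] if omitted.
#' @return Object of class `assembly_line`: list with `proteins`, `modules`
#'   (data.frame: module index, protein id, per-domain coordinates),
#'   `te_hits`, `has_starter_c`, `te_tandem`, `diagnostics`.
#' @export
assemble_line <- function(proteins, annotations = NULL) {
  stopifnot(length(proteins) >= 1)
  if (is.null(annotations)) {
    annotations <- lapply(proteins, function(p) build_modules(scan_domains(p)))
  }
  stopifnot(length(annotations) == length(proteins))
  n_prot <- length(proteins)
  rows <- list()
  te_hits <- NULL
  diagnostics <- character(0)
  idx <- 0L
  for (k in seq_len(n_prot)) {
    ann <- annotations[[k]]
    pid <- proteins[[k]]$id
    if (nrow(ann$te_hits) > 0 && k < n_prot) {
      stop("TE domain(s) on non-terminal protein '", pid, "'", call. = FALSE)
    }
    for (mod in ann$modules) {
      idx <- idx + 1L
      rows[[idx]] <- data.frame(
        module = idx, protein_id = pid,
        c_start = mod$start[1], c_end = mod$end[1],
        a_start = mod$start[2], a_end = mod$end[2],
        t_start = mod$start[3], t_end = mod$end[3],
        stringsAsFactors = FALSE)
    }
    if (k == n_prot) te_hits <- ann$te_hits
    if (length(ann$diagnostics)) {
      diagnostics <- c(diagnostics, paste0(pid, ": ", ann$diagnostics))
    }
  }
  modules <- if (length(rows)) do.call(rbind, rows) else
    data.frame(module = integer(0), protein_id = character(0))
  structure(list(
    proteins = proteins,
    modules = modules,
    te_hits = te_hits,
    has_starter_c = nrow(modules) > 0,  # module 1 begins with a C by grammar
    te_tandem = !is.null(te_hits) && nrow(te_hits) == 2L,
    diagnostics = diagnostics
  ), class = "assembly_line")
}

#' @export
print.assembly_line <- function(x, ...) {
  cat("<assembly line> ", length(x$proteins), " protein(s), ",
      nrow(x$modules), " module(s), TE tandem: ", x$te_tandem, "\n", sep = "")
  if (nrow(x$modules)) {
    per <- table(factor(x$modules$protein_id,
                        levels = vapply(x$proteins, `[[`, "", "id")))
    cat("  modules per protein: ", paste(names(per), per, sep = "=",
                                         collapse = ", "), "\n", sep = "")
  }
  if (length(x$diagnostics)) {
    cat("  diagnostics:\n", paste0("   - ", x$diagnostics, "\n"), sep = "")
  }
  invisible(x)
}

#' Extract a domain's sequence from an assembly line
#'
#' @param line An [assemble_line()] result.
#' @param module Module index (1-based along the line).
#' @param domain One of `"C"`, `"A"`, `"T"`.
#' @return Amino-acid sequence string of that domain.
#' @export
domain_sequence <- function(line, module, domain = c("C", "A", "T")) {
  domain <- match.arg(domain)
  row <- line$modules[line$modules$module == module, , drop = FALSE]
  if (nrow(row) != 1) stop("no module ", module, " in line", call. = FALSE)
  pid <- row$protein_id
  seqstr <- NULL
  for (p in line$proteins) if (p$id == pid) seqstr <- p$sequence
  cols <- switch(domain, C = c("c_start", "c_end"),
                 A = c("a_start", "a_end"), T = c("t_start", "t_end"))
  substr(seqstr, row[[cols[1]]] + 1L, row[[cols[2]]])
}

#' Write / read a domain hit table (TSV)
#'
#' Machine outputs use 0-based half-open coordinates and say so in an
#' explicit `coordinate_system` column. `read_domain_table()` is also the
#' import path for third-party domain coordinate tables (e.g. profile-HMM
#' annotation) with columns `protein_id`, `kind`, `subtype`, `start`, `end`,
#' `score`.
#'
#' @param hits data.frame with a `protein_id` column plus [scan_domains()]
#'   columns.
#' @param path File path.
#' @return `read_domain_table()`: the data.frame.
#' @export
write_domain_table <- function(hits, path) {
  hits$coordinate_system <- "0-based-half-open"
  utils::write.table(hits, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_domain_table
#' @export
read_domain_table <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("protein_id", "kind", "start", "end")
  miss <- setdiff(need, names(tab))
  if (length(miss)) {
    stop("domain table lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (is.null(tab$subtype)) tab$subtype <- "unassigned"
  if (is.null(tab$score)) tab$score <- NA_real_
  tab$coordinate_system <- NULL
  tab
}
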