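#' Read / write protein FASTA
#'
#' Standard FASTA with ids taken from the first whitespace-delimited token
#' of the header. Duplicate ids are an error naming the id; lowercase
#' residues are uppercased with a warning. Writing wraps sequence lines at
#' 60 columns; a read/write round trip preserves ids and sequences.
#'
#' @param path File path.
#' @param records List of [protein_record()].
#' @return `read_fasta()`: list of [protein_record()].
#' @export
read_fasta <- function(path) {
  set <- Biostrings::readAAStringSet(path)
  ids <- sub("\\s.*$", "", names(set))
  dup <- ids[duplicated(ids)]
  if (length(dup)) {
    stop("duplicate FASTA id(s): ", paste(unique(dup), collapse = ", "),
         call. = FALSE)
  }
  # the AA reader uppercases on ingest; detect lowercase on the raw lines
  raw <- readLines(path, warn = FALSE)
  if (any(grepl("[a-z]", raw[!startsWith(raw, ">")]))) {
    warning("lowercase residues uppercased", call. = FALSE)
  }
  seqs <- toupper(as.character(set))
  mapply(protein_record, ids, seqs, SIMPLIFY = FALSE, USE.NAMES = FALSE)
}

#' @rdname read_fasta
#' @export
write_fasta <- function(records, path) {
  set <- Biostrings::AAStringSet(vapply(records, `[[`, "", "sequence"))
  names(set) <- vapply(records, `[[`, "", "id")
  Biostrings::writeXStringSet(set, path, width = 60L)
  invisible(path)
}

#' Extract protein translations from a GenBank flat file
#'
#' Walks the feature table of each record and returns one protein per CDS
#' feature carrying a `/translation`; the id is the `/locus_tag`, falling
#' back to `/gene`, then to `<accession>_CDS<k>`. CDS features without a
#' translation are skipped with a warning; an empty feature table gives an
#' empty list with a warning. Order is preserved.
#'
#' @param path GenBank flat-file path.
#' @return list of [protein_record()].
#' @export
read_genbank_proteins <- function(path) {
  lines <- readLines(path, warn = FALSE)
  out <- list()
  accession <- "record"
  in_features <- FALSE
  cds_count <- 0L
  i <- 1L
  any_features <- FALSE
  n <- length(lines)
  while (i <= n) {
    line <- lines[i]
    if (grepl("^ACCESSION", line)) {
      accession <- strsplit(trimws(sub("^ACCESSION", "", line)), "\\s+")[[1]][1]
    } else if (grepl("^FEATURES", line)) {
      in_features <- TRUE
    } else if (grepl("^(ORIGIN|//)", line)) {
      in_features <- FALSE
    } else if (in_features && grepl("^ {5}CDS ", line)) {
      any_features <- TRUE
      cds_count <- cds_count + 1L
      gene <- locus_tag <- translation <- NULL
      j <- i + 1L
      while (j <= n && grepl("^ {6,}", lines[j]) &&
             !grepl("^ {5}[A-Za-z]", lines[j])) {
        qline <- trimws(lines[j])
        if (grepl("^/gene=", qline)) {
          gene <- gsub("\"", "", sub("^/gene=", "", qline))
        } else if (grepl("^/locus_tag=", qline)) {
          locus_tag <- gsub("\"", "", sub("^/locus_tag=", "", qline))
        } else if (grepl("^/translation=", qline)) {
          tr <- sub("^/translation=\"", "", qline)
          while (!grepl("\"$", tr) && j < n) {
            j <- j + 1L
            tr <- paste0(tr, trimws(lines[j]))
          }
          translation <- gsub("\"", "", tr)
        }
        j <- j + 1L
      }
      if (is.null(translation)) {
        warning("CDS ", cds_count, " in ", accession,
                " has no /translation; skipped", call. = FALSE)
      } else {
        id <- if (!is.null(locus_tag)) locus_tag
              else if (!is.null(gene)) gene
              else sprintf("%s_CDS%d", accession, cds_count)
        out[[length(out) + 1L]] <- protein_record(id, translation)
      }
      i <- j - 1L
    } else if (in_features && grepl("^ {5}[A-Za-z]", line)) {
      any_features <- TRUE
    }
    i <- i + 1L
  }
  if (!any_features && length(out) == 0) {
    warning("no features found in ", path, call. = FALSE)
  }
  out
}

#' Pipeline configuration
#'
#' @param proteins Path to a protein FASTA (records in biosynthetic order)
#'   or a list of [protein_record()].
#' @param panel A [reference_panel()] or `c(fasta =, tsv =)` paths.
#' @param out_dir Output directory (created if missing).
#' @param seed Seed governing every stochastic stage (a single seed, no
#'   hidden global RNG).
#' @param fatty_acids List of [fatty_acid_spec()] for congener rendering.
#' @param patristic_threshold Patristic grouping threshold (default 0.45).
#' @param nn_floor Signature-NN confidence floor (default 6).
#' @param depsi_ppm Depsi-site shift threshold in ppm (default 0.3).
#' @param glx Glx resolution for mass rendering (default `c(Glx = "Gln",
#'   Xle = "Leu")`, the more frequent resolutions; congener masses for the
#'   other isoforms can be enumerated separately).
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(proteins, panel, out_dir, seed = 1L,
                            fatty_acids = list(fatty_acid_spec(10)),
                            patristic_threshold = 0.45,
                            nn_floor = 6, depsi_ppm = 0.3,
                            glx = c(Glx = "Gln", Xle = "Leu")) {
  stopifnot(patristic_threshold > 0, nn_floor > 0, depsi_ppm > 0)
  if (is.character(proteins) && !file.exists(proteins)) {
    stop("protein FASTA not found: ", proteins, call. = FALSE)
  }
  if (is.character(panel)) {
    missing_files <- panel[!file.exists(panel)]
    if (length(missing_files)) {
      stop("reference panel file(s) not found: ",
           paste(missing_files, collapse = ", "), call. = FALSE)
    }
  }
  structure(list(proteins = proteins, panel = panel, out_dir = out_dir,
                 seed = as.integer(seed), fatty_acids = fatty_acids,
                 patristic_threshold = patristic_threshold,
                 nn_floor = nn_floor, depsi_ppm = depsi_ppm, glx = glx),
            class = "pipeline_config")
}

#' Run the annotate -> classify -> predict -> chem-verify pipeline
#'
#' Executes domain scanning and module assembly over the input proteins,
#' substrate calls (signature nearest neighbour, with phylogenetic placement
#' for ambiguous or low-confidence calls), C-domain and TE typing, the
#' co-linear peptide prediction with stereochemistry, cyclization-candidate
#' enumeration and congener formula/mass rendering. Writes a domain TSV,
#' calls TSV, prediction JSON and a human-readable summary (1-based
#' coordinates) into the output directory; machine outputs carry 0-based
#' half-open coordinates with an explicit `coordinate_system` field.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a list with `line`, `calls`, `c_classes`, `te_calls`,
#'   `prediction`, `congeners`, `paths`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  proteins <- if (is.character(config$proteins)) read_fasta(config$proteins)
              else config$proteins
  refs <- if (is.character(config$panel)) {
    read_reference_panel(config$panel[["fasta"]], config$panel[["tsv"]])
  } else config$panel
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(config$out_dir, "pipeline.log")
  logf <- function(...) cat(sprintf(...), "\n", sep = "", file = log_path,
                            append = TRUE)
  cat("", file = log_path)
  logf("nrpsmith %s | seed %d | patristic<%.2f nn_floor=%d depsi>%.2fppm",
       as.character(utils::packageVersion("nrpsmith")), config$seed,
       config$patristic_threshold, config$nn_floor, config$depsi_ppm)

  # annotate
  hit_list <- lapply(proteins, scan_domains)
  annotations <- lapply(hit_list, build_modules)
  line <- assemble_line(proteins, annotations)
  n_mod <- nrow(line$modules)
  if (n_mod == 0) stop("pipeline: no modules found", call. = FALSE)
  dom_tab <- do.call(rbind, lapply(seq_along(proteins), function(k) {
    hits <- hit_list[[k]]
    if (nrow(hits)) cbind(protein_id = proteins[[k]]$id, hits) else NULL
  }))
  write_domain_table(dom_tab, file.path(config$out_dir, "domains.tsv"))

  refs <- prepare_panel(refs)
  # classify substrates
  calls <- vector("list", n_mod)
  for (m in seq_len(n_mod)) {
    aseq <- domain_sequence(line, m, "A")
    id <- sprintf("module%d-A", m)
    sig <- extract_signature(aseq)
    nn <- call_substrate_nn(sig$signature_10, refs, floor = config$nn_floor,
                            domain_id = id)
    calls[[m]] <- if (nn$confidence == "confident") nn else {
      call_substrate_placement(aseq, refs, domain_id = id)
    }
  }
  # C typing
  c_classes <- character(n_mod)
  for (m in seq_len(n_mod)) {
    cc <- classify_c_domain(domain_sequence(line, m, "C"), refs, m,
                            domain_id = sprintf("module%d-C", m))
    c_classes[m] <- cc$class
  }
  # TE typing
  te_calls <- list()
  if (!is.null(line$te_hits) && nrow(line$te_hits) > 0) {
    last <- line$proteins[[length(line$proteins)]]
    for (t in seq_len(nrow(line$te_hits))) {
      te_seq <- substr(last$sequence, line$te_hits$start[t] + 1L,
                       line$te_hits$end[t])
      te_calls[[t]] <- classify_te(te_seq, refs, ordinal_in_tandem = t,
                                   domain_id = sprintf("TE%d", t))
    }
  }

  # predict
  pred <- predict_peptide(line, calls)
  pred$stereo <- as.character(assign_stereochemistry(c_classes))
  cyc <- enumerate_cyclization(pred, te_present = length(te_calls) > 0)
  pred$cyclization <- cyc
  chosen <- if (nrow(cyc) == 1) cyc$donor else NULL
  congeners <- enumerate_congeners(pred, config$fatty_acids,
                                   cyclization = chosen, glx = config$glx)

  # write outputs
  calls_tab <- data.frame(
    module = seq_len(n_mod),
    domain_id = vapply(calls, `[[`, "", "domain_id"),
    label = vapply(calls, `[[`, "", "label"),
    method = vapply(calls, `[[`, "", "method"),
    score = vapply(calls, function(x) as.numeric(x$score), numeric(1)),
    confidence = vapply(calls, `[[`, "", "confidence"),
    ties = vapply(calls, function(x) paste(x$ties, collapse = "/"), ""),
    c_subtype = c_classes,
    stringsAsFactors = FALSE)
  utils::write.table(calls_tab, file.path(config$out_dir, "calls.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  report <- list(
    coordinate_system = "0-based-half-open",
    seed = config$seed,
    modules = n_mod,
    te_tandem = line$te_tandem,
    residues = pred$residues,
    alternatives = pred$alternatives,
    stereo = pred$stereo,
    stereo_caveat = "predicted - deviations from the sequence-based rule have been observed",
    cyclization_candidates = cyc,
    congeners = congeners)
  jsonlite::write_json(report, file.path(config$out_dir, "prediction.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  summary_path <- file.path(config$out_dir, "summary.txt")
  sm <- c(
    sprintf("Assembly line: %d protein(s), %d module(s), TE tandem: %s",
            length(proteins), n_mod, line$te_tandem),
    sprintf("Predicted peptide: %s", paste(pred$residues, collapse = "-")),
    sprintf("Stereochemistry (predicted): %s", paste(pred$stereo, collapse = " ")),
    sprintf("Cyclization candidates: %s",
            if (nrow(cyc)) paste(sprintf("%s%d -> C-terminus (ring %d)",
                                         cyc$donor_residue, cyc$donor,
                                         cyc$ring_size), collapse = "; ")
            else "none (predicted linear)"),
    sprintf("Primary congener: %s, %s, [M+H]+ = %.4f",
            congeners$formula[1], congeners$fatty_acid[1], congeners$mz_h[1]))
  writeLines(sm, summary_path)
  logf("done: %d modules, %d congeners", n_mod, nrow(congeners))
  invisible(list(line = line, calls = calls, c_classes = c_classes,
                 te_calls = te_calls, prediction = pred,
                 congeners = congeners,
                 paths = c(domains = file.path(config$out_dir, "domains.tsv"),
                           calls = file.path(config$out_dir, "calls.tsv"),
                           prediction = file.path(config$out_dir, "prediction.json"),
                           summary = summary_path,
                           log = log_path)))
}

#' Read a pipeline configuration from YAML
#'
#' Keys mirror [pipeline_config()] arguments; `panel` is a mapping with
#' `fasta` and `tsv` paths, `fatty_acids` a list of compact descriptors
#' (see [parse_fatty_acid()]).
#'
#' @param path YAML file path.
#' @return A [pipeline_config()].
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  need <- c("proteins", "panel", "out_dir")
  miss <- setdiff(need, names(y))
  if (length(miss)) {
    stop("pipeline config lacks key(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  fa <- if (is.null(y$fatty_acids)) list(fatty_acid_spec(10))
        else lapply(y$fatty_acids, parse_fatty_acid)
  pipeline_config(
    proteins = y$proteins,
    panel = c(fasta = y$panel$fasta, tsv = y$panel$tsv),
    out_dir = y$out_dir,
    seed = if (is.null(y$seed)) 1L else y$seed,
    fatty_acids = fa,
    patristic_threshold = if (is.null(y$patristic_threshold)) 0.45
                          else y$patristic_threshold,
    nn_floor = if (is.null(y$nn_floor)) 6 else y$nn_floor,
    depsi_ppm = if (is.null(y$depsi_ppm)) 0.3 else y$depsi_ppm)
}
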