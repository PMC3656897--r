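# run code under a fixed seed, restoring the caller's RNG state afterwards:
# one seeded stream per generator call, no hidden global state left behind
.with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Point-mutate a protein sequence
#'
#' Each site is substituted independently with probability `rate` to a
#' uniformly chosen *different* residue, so the expected substitution count
#' is `rate * nchar(sequence)`.
#'
#' @param sequence Amino-acid string.
#' @param rate Per-site substitution probability in `[0, 0.5]`.
#' @return Mutated sequence string (uses the current RNG stream; seed it
#'   with `set.seed()` or via a generator config for reproducibility).
#' @export
mutate_sequence <- function(sequence, rate) {
  stopifnot(rate >= 0, rate <= 0.5)
  if (rate == 0) return(sequence)
  chars <- strsplit(sequence, "")[[1]]
  hit <- which(stats::runif(length(chars)) < rate)
  if (length(hit)) {
    repl <- .AA20[sample.int(19L, length(hit), replace = TRUE)]
    # map draw 1..19 onto the 19 residues differing from the original
    orig_idx <- match(chars[hit], .AA20)
    repl_idx <- match(repl, .AA20)
    bump <- !is.na(orig_idx) & repl_idx >= orig_idx
    repl_idx[bump] <- repl_idx[bump] + 1L
    repl_idx[repl_idx > 20L] <- repl_idx[repl_idx > 20L] - 20L
    chars[hit] <- .AA20[repl_idx]
  }
  paste0(chars, collapse = "")
}

# motif patterns a random linker must not spuriously contain
.core_motif_regexes <- c("HH...DG", "SGTTG.PK", "[IL]GG.S[LI]", "G.S.G")

.random_linker <- function(min_len = 10L, max_len = 60L) {
  repeat {
    len <- sample(min_len:max_len, 1L)
    lk <- paste0(sample(.AA20, len, replace = TRUE), collapse = "")
    if (!any(vapply(.core_motif_regexes, grepl, logical(1), x = lk))) {
      return(lk)
    }
  }
}

# deterministic class ancestors for A-domain substrate classes: the A
# scaffold diverged away from the anchor/signature regions, with a
# class-specific residue set planted at the 10 diagnostic positions.
# Ancestors depend only on (labels, class_seed), never on R's RNG, so a
# reference panel and an assembly line built from consistent configs carry
# the same classes.
.class_ancestors <- function(labels, class_seed = 1000L) {
  prof <- domain_profiles()
  tpl <- prof$A$template
  sigtpl <- signature_template()
  sig_pos <- sigtpl$idx34[sigtpl$idx10_in_34]
  spare <- c(181:204, 191:198, sigtpl$idx34)
  # draw class signatures until all pairs differ at >= 6/10 indices
  k <- length(labels)
  attempt <- 0L
  repeat {
    sigs <- lapply(seq_len(k), function(i) {
      u <- .lcg(class_seed + 37L * i + 1000003L * attempt, 10L)
      .AA20[floor(u * 20) + 1L]
    })
    ok <- TRUE
    if (k > 1) {
      for (i in seq_len(k - 1)) for (j in (i + 1):k) {
        if (sum(sigs[[i]] != sigs[[j]]) < 6) ok <- FALSE
      }
    }
    if (ok) break
    attempt <- attempt + 1L
  }
  out <- list()
  for (i in seq_len(k)) {
    anc <- .lcg_diverge(tpl, 0.20, class_seed + 97L * i, spare = spare)
    chars <- strsplit(anc, "")[[1]]
    chars[sig_pos] <- sigs[[i]]
    out[[labels[i]]] <- list(sequence = paste0(chars, collapse = ""),
                             signature_10 = paste0(sigs[[i]], collapse = ""))
  }
  out
}

#' Simulation configuration
#'
#' Defines the synthetic study conditions: an assembly line mirroring the
#' xantholysin architecture by default (modules 2/8/4 across three proteins,
#' starter C on module 1, conventional C at modules 12-13, dual C\\/E
#' elsewhere plus module 14's effect on residue 13, TE tandem), with a
#' 5% per-site query substitution rate.
#'
#' @param seed Mandatory RNG seed.
#' @param modules_per_protein Integer vector, modules per protein in order.
#' @param substrate_plan Substrate label per module (recycled from the
#'   default class labels if `NULL`).
#' @param c_subtype_plan C-domain subtype per module; default: `starter`,
#'   then `C/E` everywhere except `conventional` at the last two internal
#'   modules, mirroring the xantholysin line when the plan has 14 modules.
#' @param substrate_classes Named integer vector: reference count per
#'   substrate class label (default 4 references for each of Leu, Glu, Gln,
#'   Val, Ser, Ile).
#' @param rate Per-site substitution rate for planted (query) domains,
#'   default 0.05.
#' @param ref_rate Per-site divergence of panel references from their class
#'   ancestor, default 0.05.
#' @param te_tandem Plant a TE1+TE2 tandem on the last protein?
#' @param class_seed Seed for the deterministic class ancestors.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(seed,
                       modules_per_protein = c(2L, 8L, 4L),
                       substrate_plan = NULL,
                       c_subtype_plan = NULL,
                       substrate_classes = c(Leu = 4L, Glu = 4L, Gln = 4L,
                                             Val = 4L, Ser = 4L, Ile = 4L),
                       rate = 0.05,
                       ref_rate = 0.05,
                       te_tandem = TRUE,
                       class_seed = 1000L) {
  if (missing(seed)) stop("seed is mandatory", call. = FALSE)
  stopifnot(rate >= 0, rate <= 0.5, ref_rate >= 0, ref_rate <= 0.5,
            all(modules_per_protein >= 1))
  n_mod <- sum(modules_per_protein)
  if (is.null(substrate_plan)) {
    xtl_plan <- c("Leu", "Glu", "Gln", "Val", "Leu", "Gln", "Ser",
                  "Val", "Leu", "Gln", "Leu", "Leu", "Gln", "Ile")
    substrate_plan <- if (n_mod == 14L &&
                          all(xtl_plan %in% names(substrate_classes))) {
      xtl_plan
    } else {
      rep_len(names(substrate_classes), n_mod)
    }
  }
  stopifnot(length(substrate_plan) == n_mod,
            all(substrate_plan %in% names(substrate_classes)))
  if (is.null(c_subtype_plan)) {
    c_subtype_plan <- rep("C/E", n_mod)
    c_subtype_plan[1] <- "starter"
    if (n_mod >= 4) {
      c_subtype_plan[c(n_mod - 2L, n_mod - 1L)] <- "conventional"
    }
  }
  stopifnot(length(c_subtype_plan) == n_mod,
            all(c_subtype_plan %in% c("starter", "C/E", "conventional")))
  structure(list(seed = as.integer(seed),
                 modules_per_protein = as.integer(modules_per_protein),
                 substrate_plan = substrate_plan,
                 c_subtype_plan = c_subtype_plan,
                 substrate_classes = substrate_classes,
                 rate = rate, ref_rate = ref_rate,
                 te_tandem = isTRUE(te_tandem),
                 class_seed = as.integer(class_seed)),
            class = "sim_config")
}

#' Generate a synthetic labelled reference panel
#'
#' Each substrate class (and each C subtype and TE class) descends from a
#' distinct ancestor; references are seeded mutants of their ancestor at
#' `ref_rate` divergence. A-domain signatures in the panel TSV are extracted
#' from the mutated reference sequences with [extract_signature()], exactly
#' as a user would build a panel from characterized domains.
#'
#' @param config A [sim_config()] (>= 2 substrate classes with >= 2
#'   references each).
#' @return A [reference_panel()] covering A (one class per substrate label),
#'   C (starter / C\\/E / conventional) and TE (TE1 / TE2) references.
#' @export
make_reference_panel <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  classes <- config$substrate_classes
  if (length(classes) < 2 || any(classes < 2)) {
    stop("need >= 2 substrate classes with >= 2 references each",
         call. = FALSE)
  }
  if (length(classes) > length(known_residues())) {
    stop("more classes than the label vocabulary", call. = FALSE)
  }
  prof <- domain_profiles()
  anc <- .class_ancestors(names(classes), config$class_seed)
  .with_seed(config$seed + 1L, {
    id <- kind <- label <- sequence <- character(0)
    for (cl in names(classes)) {
      for (r in seq_len(classes[[cl]])) {
        id <- c(id, sprintf("%s-ref%d", cl, r))
        kind <- c(kind, "A")
        label <- c(label, cl)
        sequence <- c(sequence,
                      mutate_sequence(anc[[cl]]$sequence, config$ref_rate))
      }
    }
    n_sub_refs <- max(3L, ceiling(mean(classes)))
    for (sub in names(prof$C$subtypes)) {
      for (r in seq_len(n_sub_refs)) {
        id <- c(id, sprintf("C-%s-ref%d", gsub("/", "", sub), r))
        kind <- c(kind, "C")
        label <- c(label, sub)
        sequence <- c(sequence,
                      mutate_sequence(prof$C$subtypes[[sub]], config$ref_rate))
      }
    }
    for (sub in names(prof$TE$subtypes)) {
      for (r in seq_len(n_sub_refs)) {
        id <- c(id, sprintf("%s-ref%d", sub, r))
        kind <- c(kind, "TE")
        label <- c(label, sub)
        sequence <- c(sequence,
                      mutate_sequence(prof$TE$subtypes[[sub]], config$ref_rate))
      }
    }
    s34 <- rep(NA_character_, length(id))
    s10 <- rep(NA_character_, length(id))
    for (i in which(kind == "A")) {
      sig <- extract_signature(sequence[i])
      s34[i] <- sig$signature_34
      s10[i] <- sig$signature_10
    }
    reference_panel(id, kind, label, sequence,
                    signature_34 = s34, signature_10 = s10)
  })
}

#' Simulate a multi-protein NRPS assembly line with ground truth
#'
#' Proteins are concatenations of mutated domain templates — a C domain of
#' the planned subtype, an A domain of the planned substrate class, a T
#' domain per module, and a terminal TE1+TE2 tandem when flagged — joined by
#' random linkers (uniform 10-60 aa, rejection-sampled so no linker contains
#' a core motif). Every planted feature is recorded as ground truth.
#'
#' @param config A [sim_config()].
#' @return list with `proteins` (list of [protein_record()]) and `truth`:
#'   `domains` (data.frame: protein_id, kind, subtype, substrate, start,
#'   end 0-based half-open, module), `peptide`, `signature_10` per module,
#'   `stereo` (C\\/E-rule ground truth), `cyclization` (expected candidate
#'   table), `te_tandem`.
#' @export
simulate_assembly_line <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  prof <- domain_profiles()
  anc <- .class_ancestors(names(config$substrate_classes), config$class_seed)
  .with_seed(config$seed, {
    proteins <- list()
    dom_rows <- list()
    module_idx <- 0L
    sig10 <- character(0)
    n_prot <- length(config$modules_per_protein)
    for (p in seq_len(n_prot)) {
      pid <- sprintf("synprot%d", p)
      parts <- .random_linker()
      pos <- nchar(parts)  # 0-based running end
      add_domain <- function(seqstr, kind, subtype, substrate) {
        start <- pos
        parts <<- paste0(parts, seqstr)
        pos <<- pos + nchar(seqstr)
        dom_rows[[length(dom_rows) + 1L]] <<- data.frame(
          protein_id = pid, kind = kind, subtype = subtype,
          substrate = substrate, start = start, end = pos,
          module = if (kind %in% c("C", "A", "T")) module_idx else NA_integer_,
          stringsAsFactors = FALSE)
        parts <<- paste0(parts, .random_linker())
        pos <<- nchar(parts)
      }
      for (m in seq_len(config$modules_per_protein[p])) {
        module_idx <- module_idx + 1L
        subtype <- config$c_subtype_plan[module_idx]
        substrate <- config$substrate_plan[module_idx]
        add_domain(mutate_sequence(prof$C$subtypes[[subtype]], config$rate),
                   "C", subtype, NA_character_)
        a_seq <- mutate_sequence(anc[[substrate]]$sequence, config$rate)
        add_domain(a_seq, "A", "unassigned", substrate)
        sig10 <- c(sig10, anc[[substrate]]$signature_10)
        add_domain(mutate_sequence(prof$T$template, config$rate),
                   "T", "unassigned", NA_character_)
      }
      if (p == n_prot && config$te_tandem) {
        add_domain(mutate_sequence(prof$TE$subtypes$TE1, config$rate),
                   "TE", "TE1", NA_character_)
        add_domain(mutate_sequence(prof$TE$subtypes$TE2, config$rate),
                   "TE", "TE2", NA_character_)
      }
      proteins[[p]] <- protein_record(pid, parts)
    }
    peptide <- config$substrate_plan
    stereo <- assign_stereochemistry(config$c_subtype_plan)
    cyc <- enumerate_cyclization(peptide, te_present = config$te_tandem)
    list(proteins = proteins,
         truth = list(domains = do.call(rbind, dom_rows),
                      peptide = peptide,
                      signature_10 = sig10,
                      stereo = as.character(stereo),
                      cyclization = cyc,
                      te_tandem = config$te_tandem))
  })
}

#' Write a simulated line to FASTA + ground-truth JSON
#'
#' @param sim A [simulate_assembly_line()] result.
#' @param fasta_path,json_path Output paths.
#' @return Invisibly, the two paths.
#' @export
write_simulation <- function(sim, fasta_path, json_path) {
  write_fasta(sim$proteins, fasta_path)
  jsonlite::write_json(sim$truth, json_path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(c(fasta_path, json_path))
}
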