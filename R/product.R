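#' Predict the peptide sequence of an assembly line (co-linearity rule)
#'
#' Residue i of the product is the substrate call of module i; alternatives
#' from ambiguous calls are carried through, never discarded.
#'
#' @param line An [assemble_line()] result (only the module count is used).
#' @param calls List of `specificity_call` objects, one per module, in
#'   module order.
#' @return Object of class `peptide_prediction`: list with `residues`
#'   (primary labels), `alternatives` (list of character vectors, co-optimal
#'   labels other than the primary), `stereo` (filled by
#'   [assign_stereochemistry()], `"unknown"` until then).
#' @export
predict_peptide <- function(line, calls) {
  n <- nrow(line$modules)
  if (length(calls) != n) {
    stop("need one substrate call per module (", n, " modules, ",
         length(calls), " calls)", call. = FALSE)
  }
  residues <- vapply(calls, `[[`, "", "label")
  alternatives <- lapply(calls, function(cl) setdiff(cl$ties, cl$label))
  structure(list(residues = residues, alternatives = alternatives,
                 stereo = rep("unknown", n),
                 lipid_attachment = isTRUE(line$has_starter_c),
                 cyclization = NULL),
            class = "peptide_prediction")
}

#' @export
print.peptide_prediction <- function(x, ...) {
  txt <- vapply(seq_along(x$residues), function(i) {
    alt <- x$alternatives[[i]]
    if (length(alt)) paste0(x$residues[i], "/", paste(alt, collapse = "/"))
    else x$residues[i]
  }, character(1))
  cat("<peptide prediction> ", paste(txt, collapse = "-"), "\n", sep = "")
  if (!all(x$stereo == "unknown")) {
    cat("  stereo: ", paste(x$stereo, collapse = " "), "\n", sep = "")
  }
  if (!is.null(x$cyclization) && nrow(x$cyclization)) {
    cat("  cyclization candidates: ",
        paste(sprintf("donor %d (ring %d)", x$cyclization$donor,
                      x$cyclization$ring_size), collapse = "; "),
        "\n", sep = "")
  }
  invisible(x)
}

#' Assign residue stereochemistry from C-domain subtypes
#'
#' A dual condensation/epimerization (C\\/E) domain epimerizes the residue
#' loaded on the previous module's T domain: residue i-1 is D iff module i's
#' C domain is of the C\\/E type (i >= 2). Residues followed by a
#' conventional C domain, and the C-terminal residue, stay L. An unassigned
#' subtype leaves the affected residue `"unknown"`. The output is a
#' prediction: deviations from this sequence-based rule are documented among
#' natural lipopeptides, so a machine-readable caveat is attached.
#'
#' @param c_subtypes Character vector of C-domain subtypes per module
#'   (`"starter"`, `"C/E"`, `"conventional"`, `"unassigned"`).
#' @return Character vector of `"L"`/`"D"`/`"unknown"` per residue, with
#'   attribute `caveat = "predicted"`.
#' @export
assign_stereochemistry <- function(c_subtypes) {
  n <- length(c_subtypes)
  stopifnot(n >= 1)
  stereo <- rep("L", n)
  for (i in seq_len(n)[-1]) {
    stereo[i - 1] <- switch(c_subtypes[i],
      "C/E" = "D",
      "conventional" = "L",
      "starter" = "L",          # a starter beyond module 1 epimerizes nothing
      "unknown")
  }
  stereo[n] <- "L"
  structure(stereo,
            caveat = "predicted - deviations from the sequence-based rule have been observed")
}

#' Enumerate macrolactonization candidates
#'
#' With a TE domain present, every internal hydroxyl-bearing residue (Ser,
#' Thr, aThr) is a candidate lactone donor closing to the C-terminus; ring
#' size is counted inclusively (`n - donor + 1`). No candidate is
#' auto-selected: where several exist the choice needs user input or NMR
#' evidence (see [flag_depsi_sites()]) — the "last hydroxyl residue"
#' heuristic is known to fail (entolysin closes through Ser10, not Ser13).
#' Without a hydroxyl residue the product is predicted linear.
#'
#' @param pred A [predict_peptide()] result (or character vector of residues).
#' @param te_present Is a TE domain present to release/cyclize the product?
#' @return data.frame with columns `donor` (1-based residue index),
#'   `donor_residue`, `ring_size`; zero rows if linear. Candidates ordered
#'   N- to C-terminal.
#' @export
enumerate_cyclization <- function(pred, te_present = TRUE) {
  residues <- if (inherits(pred, "peptide_prediction")) pred$residues else pred
  n <- length(residues)
  stopifnot(n >= 1)
  empty <- data.frame(donor = integer(0), donor_residue = character(0),
                      ring_size = integer(0), stringsAsFactors = FALSE)
  if (!te_present || n < 2) return(empty)
  donors <- which(residues %in% .hydroxyl_residues)
  donors <- donors[donors < n]
  if (length(donors) == 0) return(empty)
  data.frame(donor = donors, donor_residue = residues[donors],
             ring_size = n - donors + 1L, stringsAsFactors = FALSE)
}

#' Enumerate congener structures with formulas and masses
#'
#' Takes the Cartesian product of per-position residue choices (primary call
#' plus alternatives) and fatty-acid variants and renders each combination
#' as a [lipopeptide_structure()] with Hill formula and monoisotopic mass.
#' The all-primary combination with the first fatty acid is listed first.
#'
#' @param pred A [predict_peptide()] result.
#' @param fatty_acids List of [fatty_acid_spec()] objects (>= 1).
#' @param cyclization Chosen lactone donor index (1-based) or `NULL` for the
#'   linear form.
#' @param glx Glx/Xle resolution passed to [compose_formula()]; unresolved
#'   ambiguity classes are an error in this mass-rendering mode.
#' @return data.frame with columns `name`, `peptide`, `fatty_acid`,
#'   `formula`, `monoisotopic_mass`, `mz_h` (`[M+H]+`), plus a `structures`
#'   attribute holding the [lipopeptide_structure()] list.
#' @export
enumerate_congeners <- function(pred, fatty_acids, cyclization = NULL,
                                glx = NULL) {
  stopifnot(inherits(pred, "peptide_prediction"), length(fatty_acids) >= 1)
  choice_sets <- lapply(seq_along(pred$residues), function(i) {
    c(pred$residues[i], pred$alternatives[[i]])
  })
  # row 1 is the all-primary combination
  grid <- expand.grid(lapply(choice_sets, seq_along))
  rows <- list()
  structures <- list()
  k <- 0L
  for (fa_i in seq_along(fatty_acids)) {
    for (g in seq_len(nrow(grid))) {
      residues <- vapply(seq_along(choice_sets), function(pos) {
        choice_sets[[pos]][grid[[pos]][g]]
      }, character(1))
      st <- lipopeptide_structure(residues, stereo = pred$stereo,
                                  fatty_acid = fatty_acids[[fa_i]],
                                  lactone_donor = cyclization)
      comp <- compose_formula(st, glx = glx)
      k <- k + 1L
      structures[[k]] <- st
      rows[[k]] <- data.frame(
        name = paste0("congener_", k),
        peptide = paste(residues, collapse = "-"),
        fatty_acid = format(fatty_acids[[fa_i]]),
        formula = hill_formula(comp),
        monoisotopic_mass = monoisotopic_mass(comp, digits = 4),
        mz_h = adduct_mz(comp, "[M+H]+"),
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  out$name[1] <- "primary"
  attr(out, "structures") <- structures
  out
}

#' Flag candidate depsi-bond donor sites from chemical shifts
#'
#' The protons neighbouring a depsi (lactone ester) bond experience an
#' anisotropic deshielding by the ester carbonyl: a hydroxyl-residue H-beta
#' site whose observed shifts lie downfield of the random-coil values by
#' more than `threshold_ppm` on average is flagged as a likely donor. Sites
#' without a random-coil reference are skipped with a warning — in
#' particular this lets the fatty-acid 3-OH site be tested and (absent a
#' strong downfield shift) excluded.
#'
#' @param shifts data.frame with columns `residue_index`, `atom`,
#'   `shift_ppm` (one row per observed resonance; geminal pairs are two rows).
#' @param random_coil data.frame with columns `residue`, `atom`,
#'   `shift_ppm` giving random-coil reference shifts, plus the per-site
#'   residue mapping column `residue_index` joined through `site_residues`.
#' @param site_residues Named character vector mapping residue index (as
#'   string) to residue name, used to look up random-coil values.
#' @param threshold_ppm Mean downfield deviation needed to flag a site
#'   (default 0.3 ppm).
#' @return data.frame per site: `residue_index`, `atom`, `mean_observed`,
#'   `mean_random_coil`, `deviation_ppm`, `flagged`.
#' @export
flag_depsi_sites <- function(shifts, random_coil, site_residues,
                             threshold_ppm = 0.3) {
  stopifnot(all(c("residue_index", "atom", "shift_ppm") %in% names(shifts)),
            all(c("residue", "atom", "shift_ppm") %in% names(random_coil)),
            threshold_ppm > 0)
  key <- interaction(shifts$residue_index, shifts$atom, drop = TRUE)
  out <- list()
  for (k in levels(key)) {
    rows <- shifts[key == k, , drop = FALSE]
    ridx <- rows$residue_index[1]
    atom <- rows$atom[1]
    resname <- unname(site_residues[as.character(ridx)])
    rc <- if (is.na(resname)) random_coil[0, , drop = FALSE] else
      random_coil[random_coil$residue == resname & random_coil$atom == atom, ,
                  drop = FALSE]
    if (nrow(rc) == 0) {
      warning("no random-coil reference for site ", ridx, " ", atom,
              "; skipped", call. = FALSE)
      next
    }
    dev <- mean(rows$shift_ppm) - mean(rc$shift_ppm)
    out[[length(out) + 1L]] <- data.frame(
      residue_index = ridx, atom = atom,
      mean_observed = mean(rows$shift_ppm),
      mean_random_coil = mean(rc$shift_ppm),
      deviation_ppm = dev,
      flagged = dev > threshold_ppm,
      stringsAsFactors = FALSE)
  }
  if (length(out) == 0) {
    return(data.frame(residue_index = integer(0), atom = character(0),
                      mean_observed = numeric(0), mean_random_coil = numeric(0),
                      deviation_ppm = numeric(0), flagged = logical(0)))
  }
  do.call(rbind, out)
}

#' Packaged random-coil chemical-shift references
#'
#' Minimal random-coil reference table for the depsi-site heuristic,
#' covering the hydroxyl-residue H-beta sites (the Ser H-beta geminal pair
#' at 3.79 and 3.95 ppm at minimum).
#'
#' @return data.frame with columns `residue`, `atom`, `shift_ppm`, `source`.
#' @export
random_coil_reference <- function() {
  utils::read.delim(system.file("extdata", "random_coil_shifts.tsv",
                                package = "nrpsmith"),
                    stringsAsFactors = FALSE)
}

#' Classify alkene geometry from flanking 13C shift changes
#'
#' In a cis double bond the flanking allylic carbons are sterically
#' compressed and shifted upfield relative to the saturated analog; in a
#' trans bond they move downfield. Both deltas negative therefore indicates
#' cis, both positive trans, and a mixed sign pattern is ambiguous.
#'
#' @param delta_gamma_ppm,delta_zeta_ppm Observed minus saturated-analog
#'   13C shifts (ppm) of the two carbons flanking the double bond.
#' @return `"cis"`, `"trans"` or `"ambiguous"`.
#' @examples
#' classify_alkene_geometry(35.53 - 37.91, 27.28 - 29.60)  # "cis"
#' @export
classify_alkene_geometry <- function(delta_gamma_ppm, delta_zeta_ppm) {
  stopifnot(is.finite(delta_gamma_ppm), is.finite(delta_zeta_ppm))
  if (delta_gamma_ppm < 0 && delta_zeta_ppm < 0) return("cis")
  if (delta_gamma_ppm > 0 && delta_zeta_ppm > 0) return("trans")
  "ambiguous"
}

#' Read a congener table (TSV)
#'
#' Columns: `name`, `sequence` (hyphen-separated 3-letter codes),
#' `fatty_acid` (compact descriptor, see [parse_fatty_acid()]),
#' `lactone_donor` (1-based index, empty for linear).
#'
#' @param path File path.
#' @return data.frame.
#' @export
read_congener_table <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("name", "sequence", "fatty_acid", "lactone_donor")
  miss <- setdiff(need, names(tab))
  if (length(miss)) {
    stop("congener table lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  tab
}

#' Build a lipopeptide structure from a congener-table row
#'
#' @param row One row of a [read_congener_table()] data.frame.
#' @return A [lipopeptide_structure()].
#' @export
structure_from_congener <- function(row) {
  residues <- strsplit(row$sequence, "-", fixed = TRUE)[[1]]
  fa <- parse_fatty_acid(row$fatty_acid)
  donor <- if (is.na(row$lactone_donor) || row$lactone_donor == "") NULL
           else as.integer(row$lactone_donor)
  lipopeptide_structure(residues, fatty_acid = fa, lactone_donor = donor)
}
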