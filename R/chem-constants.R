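#' Atomic mass constants
#'
#' Monoisotopic and average atomic masses (IUPAC 2021 values) plus the proton
#' mass used for protonated adducts. The proton mass (1.007276 Da), not the
#' hydrogen-atom mass, is used for `[M+zH]z+` species so that computed m/z
#' values agree with high-resolution MS expected values to 4 decimals.
#'
#' @return A list with components `monoisotopic` (named numeric vector, Da),
#'   `average` (named numeric vector, Da), `proton` and `electron` (Da).
#' @examples
#' chem_constants()$monoisotopic[["O"]]
#' @export
chem_constants <- function() {
  list(
    monoisotopic = c(
      C  = 12.0,
      H  = 1.00782503207,
      N  = 14.0030740048,
      O  = 15.9949146196,
      S  = 31.97207100,
      P  = 30.97376163,
      Na = 22.9897692809,
      K  = 38.96370668
    ),
    average = c(
      C  = 12.011,
      H  = 1.008,
      N  = 14.007,
      O  = 15.999,
      S  = 32.06,
      P  = 30.974,
      Na = 22.990,
      K  = 39.098
    ),
    proton = 1.007276,
    electron = 0.000548579909
  )
}

# Residue compositions as incorporated in a peptide chain (amino acid minus
# one water). Non-proteinogenic entries cover residues occurring in
# Pseudomonas lipopeptide assembly lines: allo-threonine (aThr),
# 2,3-dehydro-2-aminobutyric acid (Dhb), 2,4-diaminobutyric acid (Dab) and
# 3-hydroxyaspartate (OH-Asp). Glx is an ambiguity class (Glu or Gln) and
# Xle an unresolved Leu/Ile; neither has a composition of its own.
.residue_table <- list(
  Gly = c(C = 2,  H = 3,  N = 1, O = 1),
  Ala = c(C = 3,  H = 5,  N = 1, O = 1),
  Ser = c(C = 3,  H = 5,  N = 1, O = 2),
  Pro = c(C = 5,  H = 7,  N = 1, O = 1),
  Val = c(C = 5,  H = 9,  N = 1, O = 1),
  Thr = c(C = 4,  H = 7,  N = 1, O = 2),
  Cys = c(C = 3,  H = 5,  N = 1, O = 1, S = 1),
  Leu = c(C = 6,  H = 11, N = 1, O = 1),
  Ile = c(C = 6,  H = 11, N = 1, O = 1),
  Asn = c(C = 4,  H = 6,  N = 2, O = 2),
  Asp = c(C = 4,  H = 5,  N = 1, O = 3),
  Gln = c(C = 5,  H = 8,  N = 2, O = 2),
  Lys = c(C = 6,  H = 12, N = 2, O = 1),
  Glu = c(C = 5,  H = 7,  N = 1, O = 3),
  Met = c(C = 5,  H = 9,  N = 1, O = 1, S = 1),
  His = c(C = 6,  H = 7,  N = 3, O = 1),
  Phe = c(C = 9,  H = 9,  N = 1, O = 1),
  Arg = c(C = 6,  H = 12, N = 4, O = 1),
  Tyr = c(C = 9,  H = 9,  N = 1, O = 2),
  Trp = c(C = 11, H = 10, N = 2, O = 1),
  aThr  = c(C = 4, H = 7, N = 1, O = 2),
  Dhb   = c(C = 4, H = 5, N = 1, O = 1),
  Dab   = c(C = 4, H = 8, N = 2, O = 1),
  `OH-Asp` = c(C = 4, H = 5, N = 1, O = 4)
)

.ambiguous_residues <- list(
  Glx = c("Glu", "Gln"),
  Xle = c("Leu", "Ile")
)

# Residues whose side chain carries the hydroxyl that can donate a depsi
# (macrolactone ester) bond.
.hydroxyl_residues <- c("Ser", "Thr", "aThr")

#' Registry of residue compositions
#'
#' @param name Optional residue name (3-letter code). If omitted, the whole
#'   registry is returned.
#' @return With `name`, an [element_composition()] of the residue as
#'   incorporated in a chain (amino acid minus one water); otherwise a named
#'   list of compositions.
#' @examples
#' residue_composition("Leu")
#' @export
residue_composition <- function(name) {
  if (missing(name)) {
    return(lapply(.residue_table, element_composition))
  }
  if (name %in% names(.ambiguous_residues)) {
    stop("residue '", name, "' is an ambiguity class (",
         paste(.ambiguous_residues[[name]], collapse = "/"),
         "); resolve it before composing a formula", call. = FALSE)
  }
  comp <- .residue_table[[name]]
  if (is.null(comp)) {
    stop("unknown residue name: '", name, "'", call. = FALSE)
  }
  element_composition(comp)
}

#' Residue names known to the registry
#' @param include_ambiguous Include the ambiguity classes Glx and Xle.
#' @return Character vector of 3-letter codes.
#' @export
known_residues <- function(include_ambiguous = TRUE) {
  out <- names(.residue_table)
  if (include_ambiguous) out <- c(out, names(.ambiguous_residues))
  out
}
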