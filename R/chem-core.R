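#' Element compositions
#'
#' An element composition is a mapping from element symbols to non-negative
#' integer counts, the basic currency of molecular-formula algebra. Addition
#' and subtraction are element-wise; subtraction that would drive any count
#' negative is an error (a molecule cannot lose atoms it does not have).
#'
#' @param counts Named integer vector (or arguments passed as `C = 84, ...`).
#' @param ... Individual element counts, alternative to `counts`.
#' @return An object of class `elem_comp`.
#' @examples
#' water <- element_composition(H = 2, O = 1)
#' element_composition(C = 84, H = 146, N = 18, O = 23)
#' @export
element_composition <- function(counts = NULL, ...) {
  if (is.null(counts)) counts <- c(...)
  if (length(counts) == 0) {
    counts <- integer(0)
    names(counts) <- character(0)
  }
  if (is.null(names(counts)) || any(names(counts) == "")) {
    stop("element counts must be named", call. = FALSE)
  }
  if (any(counts < 0)) {
    stop("element counts must be non-negative", call. = FALSE)
  }
  if (any(counts != round(counts))) {
    stop("element counts must be integers", call. = FALSE)
  }
  counts <- counts[counts > 0]
  # collapse duplicates, keep deterministic (alphabetical) storage order
  counts <- tapply(as.integer(counts), names(counts), sum)
  counts <- counts[order(names(counts))]
  structure(as.integer(counts), names = names(counts), class = "elem_comp")
}

#' @export
`+.elem_comp` <- function(e1, e2) {
  all_el <- union(names(e1), names(e2))
  v <- stats::setNames(integer(length(all_el)), all_el)
  v[names(e1)] <- v[names(e1)] + unclass(e1)
  v[names(e2)] <- v[names(e2)] + unclass(e2)
  element_composition(v)
}

#' @export
`-.elem_comp` <- function(e1, e2) {
  all_el <- union(names(e1), names(e2))
  v <- stats::setNames(integer(length(all_el)), all_el)
  v[names(e1)] <- v[names(e1)] + unclass(e1)
  v[names(e2)] <- v[names(e2)] - unclass(e2)
  if (any(v < 0)) {
    neg <- names(v)[v < 0]
    stop("composition subtraction would give negative counts for: ",
         paste(neg, collapse = ", "), call. = FALSE)
  }
  element_composition(v)
}

#' @export
`==.elem_comp` <- function(e1, e2) {
  identical(unclass(element_composition(unclass(e1))),
            unclass(element_composition(unclass(e2))))
}

#' @export
format.elem_comp <- function(x, ...) hill_formula(x)

#' @export
print.elem_comp <- function(x, ...) {
  cat("<element composition> ", hill_formula(x), "\n", sep = "")
  invisible(x)
}

#' Render a composition in Hill order
#'
#' Hill convention: carbon first, hydrogen second, all other elements
#' alphabetically. Counts of 1 are left implicit.
#'
#' @param comp An [element_composition()].
#' @return Single string, e.g. `"C84H146N18O23"`.
#' @export
hill_formula <- function(comp) {
  v <- unclass(comp)
  el <- names(v)
  ord <- c(intersect(c("C", "H"), el), sort(setdiff(el, c("C", "H"))))
  paste0(vapply(ord, function(e) {
    if (v[[e]] == 1) e else paste0(e, v[[e]])
  }, character(1)), collapse = "")
}

#' Parse a molecular formula string
#'
#' @param formula String such as `"C84H146N18O23"` or `"H2O"`.
#' @return An [element_composition()].
#' @export
parse_formula <- function(formula) {
  stopifnot(is.character(formula), length(formula) == 1)
  m <- gregexpr("[A-Z][a-z]?[0-9]*", formula)[[1]]
  toks <- regmatches(formula, gregexpr("[A-Z][a-z]?[0-9]*", formula))[[1]]
  if (sum(attr(m, "match.length")) != nchar(formula) || length(toks) == 0) {
    stop("cannot parse formula: '", formula, "'", call. = FALSE)
  }
  el <- sub("[0-9]*$", "", toks)
  n <- sub("^[A-Za-z]+", "", toks)
  n <- ifelse(n == "", 1L, as.integer(n))
  element_composition(stats::setNames(n, el))
}

# fixed small-molecule compositions
.comp_water <- function() element_composition(H = 2, O = 1)

#' Fatty-acid specification
#'
#' A 3-hydroxy fatty acid as attached during NRPS lipoinitiation. Its neutral
#' composition is CnH(2n-2d)O3 for `n` carbons and `d` double bonds.
#'
#' @param carbons Chain length (>= 2).
#' @param double_bonds List of `list(position =, geometry =)` entries;
#'   geometry one of `"cis"`, `"trans"`, `"unknown"`. Positions must be
#'   below `carbons`.
#' @param hydroxyl_position Position of the hydroxyl (3 for all beta-hydroxy
#'   acids handled here).
#' @return Object of class `fatty_acid`.
#' @examples
#' fatty_acid_spec(10)                                     # 3-hydroxydecanoate
#' fatty_acid_spec(12, list(list(position = 5, geometry = "cis")))
#' @export
fatty_acid_spec <- function(carbons, double_bonds = list(), hydroxyl_position = 3) {
  stopifnot(length(carbons) == 1, carbons >= 2, carbons == round(carbons))
  for (db in double_bonds) {
    if (!is.null(db$position) && !is.na(db$position) &&
        (db$position >= carbons || db$position < 2)) {
      stop("double-bond position must lie within the chain (2..carbons-1)",
           call. = FALSE)
    }
    if (is.null(db$geometry)) db$geometry <- "unknown"
    if (!db$geometry %in% c("cis", "trans", "unknown")) {
      stop("double-bond geometry must be cis, trans or unknown", call. = FALSE)
    }
  }
  structure(list(carbons = as.integer(carbons),
                 hydroxyl_position = as.integer(hydroxyl_position),
                 double_bonds = double_bonds),
            class = "fatty_acid")
}

#' @rdname fatty_acid_spec
#' @param fa A `fatty_acid` object.
#' @return `fatty_acid_composition()`: the neutral-acid [element_composition()].
#' @export
fatty_acid_composition <- function(fa) {
  stopifnot(inherits(fa, "fatty_acid"))
  d <- length(fa$double_bonds)
  element_composition(C = fa$carbons, H = 2L * fa$carbons - 2L * d, O = 3L)
}

#' Parse a compact fatty-acid descriptor
#'
#' Format: `C<carbons>:<double bond count>[(<pos><c|t|x>...)]-3OH`, e.g.
#' `"C10:0-3OH"` or `"C12:1(5c)-3OH"` (c = cis, t = trans, x = unknown).
#'
#' @param txt Descriptor string; `""` or `NA` give `NULL` (no lipid).
#' @return A [fatty_acid_spec()] or `NULL`.
#' @export
parse_fatty_acid <- function(txt) {
  if (is.null(txt) || is.na(txt) || !nzchar(txt)) return(NULL)
  m <- regmatches(txt, regexec(
    "^C([0-9]+):([0-9]+)(?:\\(([^)]*)\\))?-3OH$", txt))[[1]]
  if (length(m) == 0) stop("cannot parse fatty acid: '", txt, "'", call. = FALSE)
  carbons <- as.integer(m[2])
  ndb <- as.integer(m[3])
  dbs <- list()
  if (nzchar(m[4])) {
    for (tok in strsplit(m[4], ",", fixed = TRUE)[[1]]) {
      g <- regmatches(tok, regexec("^([0-9]+)([ctx])$", tok))[[1]]
      if (length(g) == 0) stop("bad double-bond token: '", tok, "'", call. = FALSE)
      dbs[[length(dbs) + 1]] <- list(
        position = as.integer(g[2]),
        geometry = switch(g[3], c = "cis", t = "trans", x = "unknown"))
    }
  }
  if (length(dbs) != ndb) {
    if (length(dbs) == 0) {
      dbs <- replicate(ndb, list(position = NA, geometry = "unknown"),
                       simplify = FALSE)
    } else {
      stop("double-bond count disagrees with listed positions in '", txt, "'",
           call. = FALSE)
    }
  }
  fatty_acid_spec(carbons, dbs)
}

#' @export
format.fatty_acid <- function(x, ...) {
  ndb <- length(x$double_bonds)
  pos <- if (ndb) paste0("(", paste(vapply(x$double_bonds, function(db) {
    paste0(db$position, substr(db$geometry, 1, 1))
  }, character(1)), collapse = ","), ")") else ""
  paste0("C", x$carbons, ":", ndb, pos, "-3OH")
}

#' Lipopeptide structure
#'
#' An ordered peptide chain with optional N-terminal fatty acylation and an
#' optional macrolactone between a hydroxyl-bearing donor residue (Ser, Thr,
#' aThr) or the fatty-acid 3-OH and the C-terminal carboxyl.
#'
#' @param residues Character vector of residue 3-letter codes (N- to C-terminal).
#' @param stereo Per-residue configuration, `"L"`, `"D"` or `"unknown"`;
#'   recycled if length 1.
#' @param fatty_acid A [fatty_acid_spec()] or `NULL`.
#' @param lactone_donor 1-based residue index of the lactone donor, the string
#'   `"fatty_acid"` for closure through the lipid 3-OH, or `NULL` for a linear
#'   peptide.
#' @return Object of class `lipopeptide`.
#' @examples
#' xanA <- lipopeptide_structure(
#'   c("Leu","Glu","Gln","Val","Leu","Gln","Ser","Val","Leu","Gln","Leu","Leu","Gln","Ile"),
#'   fatty_acid = fatty_acid_spec(10), lactone_donor = 7)
#' hill_formula(compose_formula(xanA))
#' @export
lipopeptide_structure <- function(residues, stereo = "unknown",
                                  fatty_acid = NULL, lactone_donor = NULL) {
  stopifnot(length(residues) >= 1)
  stereo <- rep_len(stereo, length(residues))
  if (!all(stereo %in% c("L", "D", "unknown"))) {
    stop("stereo flags must be L, D or unknown", call. = FALSE)
  }
  if (!is.null(fatty_acid)) stopifnot(inherits(fatty_acid, "fatty_acid"))
  if (!is.null(lactone_donor)) {
    if (identical(lactone_donor, "fatty_acid")) {
      if (is.null(fatty_acid)) {
        stop("lactone through the fatty-acid 3-OH requires a fatty acid",
             call. = FALSE)
      }
    } else {
      stopifnot(length(lactone_donor) == 1, lactone_donor >= 1,
                lactone_donor <= length(residues))
      donor <- residues[[lactone_donor]]
      if (!donor %in% .hydroxyl_residues) {
        stop("lactone donor residue ", lactone_donor, " (", donor,
             ") carries no side-chain hydroxyl", call. = FALSE)
      }
      lactone_donor <- as.integer(lactone_donor)
    }
  }
  structure(list(residues = as.character(residues), stereo = stereo,
                 fatty_acid = fatty_acid, lactone_donor = lactone_donor),
            class = "lipopeptide")
}

#' @export
format.lipopeptide <- function(x, ...) {
  pep <- paste(x$residues, collapse = "-")
  fa <- if (!is.null(x$fatty_acid)) paste0(format(x$fatty_acid), "-") else ""
  cyc <- if (!is.null(x$lactone_donor)) {
    paste0(" [lactone ", if (identical(x$lactone_donor, "fatty_acid"))
      "FA-3OH" else paste0("donor ", x$lactone_donor), " -> C-term]")
  } else " [linear]"
  paste0(fa, pep, cyc)
}

#' @export
print.lipopeptide <- function(x, ...) {
  cat("<lipopeptide> ", format(x), "\n", sep = "")
  invisible(x)
}

#' Molecular formula of a lipopeptide structure
#'
#' Sums chain residue compositions plus one water for the termini, adds the
#' fatty-acid composition minus one water for the N-acyl amide, and removes
#' one more water if the structure is lactonized.
#'
#' @param structure A [lipopeptide_structure()].
#' @param glx Resolution policy for Glx/Xle ambiguity classes: a named
#'   character vector mapping class to residue (e.g. `c(Glx = "Gln")`), or
#'   `NULL` to raise an error when an ambiguity class is present.
#' @return An [element_composition()].
#' @export
compose_formula <- function(structure, glx = NULL) {
  stopifnot(inherits(structure, "lipopeptide"))
  res <- structure$residues
  amb <- res %in% names(.ambiguous_residues)
  if (any(amb)) {
    if (is.null(glx)) {
      stop("unresolved ambiguity class at residue(s) ",
           paste(which(amb), collapse = ", "),
           " (", paste(unique(res[amb]), collapse = ", "),
           "); supply glx = c(Glx = \"Glu\") or similar", call. = FALSE)
    }
    res[amb] <- glx[res[amb]]
    if (anyNA(res)) stop("glx resolution missing for some classes", call. = FALSE)
  }
  comp <- Reduce(`+`, lapply(res, residue_composition)) + .comp_water()
  if (!is.null(structure$fatty_acid)) {
    comp <- comp + fatty_acid_composition(structure$fatty_acid) - .comp_water()
  }
  if (!is.null(structure$lactone_donor)) {
    comp <- comp - .comp_water()
  }
  comp
}

#' Monoisotopic mass of a composition
#'
#' @param comp An [element_composition()] (or formula string).
#' @param digits If non-`NULL`, round half-even to this many decimals
#'   (high-resolution MS reports typically print 4).
#' @return Mass in Da.
#' @examples
#' monoisotopic_mass(parse_formula("H2O"), digits = 4)
#' @export
monoisotopic_mass <- function(comp, digits = NULL) {
  if (is.character(comp)) comp <- parse_formula(comp)
  stopifnot(inherits(comp, "elem_comp"))
  masses <- chem_constants()$monoisotopic
  unknown <- setdiff(names(comp), names(masses))
  if (length(unknown)) {
    stop("unknown element(s): ", paste(unknown, collapse = ", "), call. = FALSE)
  }
  m <- sum(unclass(comp) * masses[names(comp)])
  if (!is.null(digits)) m <- round(m, digits) # round() is half-even
  m
}

# cation masses used for adducts: proton per convention; metal cations are
# atom minus one electron
.adduct_registry <- function() {
  cc <- chem_constants()
  list(
    H  = cc$proton,
    Na = cc$monoisotopic[["Na"]] - cc$electron,
    K  = cc$monoisotopic[["K"]] - cc$electron
  )
}

#' Adduct m/z of a neutral composition
#'
#' @param comp [element_composition()] or formula string of the neutral
#'   molecule M.
#' @param adduct Adduct descriptor: `"[M+H]+"`, `"[M+Na]+"`, `"[M+2H]2+"`,
#'   generally `"[M+<n><ion>]<z>+"`.
#' @param digits Decimals for half-even rounding (default 4, matching
#'   high-resolution MS figure precision); `NULL` for full precision.
#' @return m/z in Da per unit charge.
#' @examples
#' adduct_mz("C84H146N18O23", "[M+H]+")
#' @export
adduct_mz <- function(comp, adduct = "[M+H]+", digits = 4) {
  if (is.character(comp)) comp <- parse_formula(comp)
  m <- regmatches(adduct, regexec(
    "^\\[M(\\+[0-9]*[A-Z][a-z]?)+\\]([0-9]*)\\+$", adduct))[[1]]
  if (length(m) == 0) stop("cannot parse adduct: '", adduct, "'", call. = FALSE)
  z <- if (nzchar(m[3])) as.integer(m[3]) else 1L
  if (z < 1) stop("charge z must be >= 1", call. = FALSE)
  ions <- regmatches(adduct, gregexpr("\\+[0-9]*[A-Z][a-z]?", adduct))[[1]]
  reg <- .adduct_registry()
  added <- 0
  for (ion in ions) {
    g <- regmatches(ion, regexec("^\\+([0-9]*)([A-Z][a-z]?)$", ion))[[1]]
    n <- if (nzchar(g[2])) as.integer(g[2]) else 1L
    if (!g[3] %in% names(reg)) {
      stop("unknown adduct ion: '", g[3], "'", call. = FALSE)
    }
    added <- added + n * reg[[g[3]]]
  }
  mz <- (monoisotopic_mass(comp) + added) / z
  if (!is.null(digits)) mz <- round(mz, digits)
  mz
}

#' Built-in mass-delta hypothesis table
#'
#' Compositional differences commonly observed between lipopeptide congeners:
#' CH2 (one methylene: Ile/Val-type residue exchange or fatty-acid chain
#' +/-CH2), C2H2 (two extra chain carbons with one unsaturation, e.g.
#' C10:0 -> C12:1), H2O (lactone ring opening / linear vs cyclic) and Na/H
#' exchange between adduct series.
#'
#' @return data.frame with columns `delta_formula`, `delta_mass`,
#'   `interpretation`.
#' @export
mass_delta_table <- function() {
  data.frame(
    delta_formula = c("CH2", "C2H2", "H2O", "Na-H"),
    delta_mass = c(
      monoisotopic_mass("CH2"),
      monoisotopic_mass("C2H2"),
      monoisotopic_mass("H2O"),
      chem_constants()$monoisotopic[["Na"]] - chem_constants()$monoisotopic[["H"]]
    ),
    interpretation = c(
      "one methylene: Ile<->Val (or Leu<->Val) residue exchange, or fatty-acyl chain +/-CH2",
      "two chain carbons with one unsaturation: e.g. C10:0 -> C12:1 fatty acid",
      "one water: lactone ring opening (linear vs cyclic form)",
      "sodium/proton exchange between adduct series"
    ),
    stringsAsFactors = FALSE
  )
}

#' Explain an observed mass difference
#'
#' Matches `|delta|` against a table of compositional hypotheses and returns
#' matches within `tolerance`, ranked by absolute error. A delta of (near)
#' zero returns the identity hypothesis.
#'
#' @param delta Observed mass difference in Da (sign ignored).
#' @param tolerance Matching tolerance in Da (> 0).
#' @param table Hypothesis table, by default [mass_delta_table()]; users can
#'   supply an extended table with the same columns.
#' @return data.frame of matching hypotheses with an `error` column; zero
#'   rows if nothing matches.
#' @examples
#' mass_delta_explain(14.02, 0.05)
#' @export
mass_delta_explain <- function(delta, tolerance = 0.02,
                               table = mass_delta_table()) {
  stopifnot(tolerance > 0)
  if (abs(delta) <= tolerance) {
    return(data.frame(delta_formula = "none", delta_mass = 0,
                      interpretation = "identity / no compositional change",
                      error = abs(delta), stringsAsFactors = FALSE))
  }
  err <- abs(abs(delta) - table$delta_mass)
  hit <- table[err <= tolerance, , drop = FALSE]
  hit$error <- err[err <= tolerance]
  hit[order(hit$error), , drop = FALSE]
}

#' Mass spread of unresolved Glx residues
#'
#' Each unresolved Glx contributes a Gln-vs-Glu uncertainty of 0.98402 Da
#' (NH vs O). Returns the monoisotopic masses of the all-Gln and all-Glu
#' resolutions of a structure and the spread between them.
#'
#' @param structure A [lipopeptide_structure()] possibly containing Glx.
#' @return list with `mass_all_gln`, `mass_all_glu`, `spread`, `n_glx`.
#' @export
glx_mass_spread <- function(structure) {
  n_glx <- sum(structure$residues == "Glx")
  m_gln <- monoisotopic_mass(compose_formula(structure, glx = c(Glx = "Gln")))
  m_glu <- monoisotopic_mass(compose_formula(structure, glx = c(Glx = "Glu")))
  list(mass_all_gln = m_gln, mass_all_glu = m_glu,
       spread = abs(m_glu - m_gln), n_glx = n_glx)
}
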