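# Synthetic consensus scaffolds for NRPS core domains.
#
# Each domain kind (C, A, T, TE) gets a fixed scaffold sequence embedding the
# field's core motif at a fixed offset: C-domain HHxxxDG, A-domain A3
# "SGTTGxPK"-like core, T-domain (I/L)GGxS(L/I) with the invariant
# phosphopantetheinylated Ser, TE GxSxG. Scaffolds are deterministic
# constants drawn from an internal linear congruential generator so they do
# not depend on (or disturb) the user's RNG state. They are synthetic: they
# exercise the same detectors as natural domains without copying any natural
# sequence.

.AA20 <- c("A","C","D","E","F","G","H","I","K","L",
           "M","N","P","Q","R","S","T","V","W","Y")

# Park-Miller minimal standard LCG; returns n draws in [0, 1)
.lcg <- function(seed, n) {
  state <- as.double(seed %% 2147483647L)
  if (state == 0) state <- 1
  out <- numeric(n)
  for (i in seq_len(n)) {
    state <- (state * 16807) %% 2147483647
    out[i] <- state / 2147483647
  }
  out
}

.lcg_protein <- function(seed, n) {
  paste0(.AA20[floor(.lcg(seed, n) * 20) + 1L], collapse = "")
}

.plant <- function(seq, motif, at) {
  # at: 1-based start of motif within seq
  paste0(substr(seq, 1, at - 1L), motif,
         substr(seq, at + nchar(motif), nchar(seq)))
}

# deterministically mutate a fraction of positions, sparing `spare` (1-based
# index vector); used to derive subtype/class variants of a base scaffold
.lcg_diverge <- function(seq, frac, seed, spare = integer(0)) {
  n <- nchar(seq)
  u <- .lcg(seed, 2L * n)
  pick <- setdiff(which(u[seq_len(n)] < frac), spare)
  chars <- strsplit(seq, "")[[1]]
  repl <- .AA20[floor(u[n + pick] * 20) + 1L]
  # force a real substitution
  same <- repl == chars[pick]
  repl[same] <- .AA20[(match(repl[same], .AA20) %% 20L) + 1L]
  chars[pick] <- repl
  paste0(chars, collapse = "")
}

# cache: profiles are pure functions of constants
.profile_env <- new.env(parent = emptyenv())

#' Packaged NRPS domain profiles
#'
#' Motif-anchored detection profiles for the four core domain kinds. Each
#' profile carries the scaffold (template) sequence, the nominal domain
#' length, a 24-residue anchor subsequence at a fixed offset (searched with
#' up to `max_mismatch` mismatches) and subtype variant templates where the
#' kind has subtypes (C: starter / dual C\\/E / conventional; TE: TE1 / TE2).
#' Subtype variants diverge from the base scaffold everywhere except the
#' anchor region and core motif, so one anchor detects every subtype.
#'
#' @return Named list of profiles (kinds `C`, `A`, `T`, `TE`).
#' @export
domain_profiles <- function() {
  if (!is.null(.profile_env$profiles)) return(.profile_env$profiles)

  c_base <- .plant(.lcg_protein(101L, 450L), "HHAILDG", 131L)
  a_base <- .plant(.lcg_protein(202L, 500L), "SGTTGQPK", 191L)
  t_base <- .plant(.lcg_protein(303L, 80L),  "LGGHSL",  31L)
  te_base <- .plant(.lcg_protein(404L, 250L), "GHSQG",  81L)

  anchor <- function(seq, off, len = 24L) substr(seq, off, off + len - 1L)

  # regions to keep intact when deriving subtype variants: anchor + motif
  c_spare <- 121:151
  te_spare <- 71:101
  prof <- list(
    C = list(
      kind = "C", template = c_base, length = 450L,
      anchor = anchor(c_base, 121L), anchor_offset = 121L, max_mismatch = 9L,
      subtypes = list(
        starter        = .lcg_diverge(c_base, 0.25, 111L, c_spare),
        `C/E`          = .lcg_diverge(c_base, 0.25, 112L, c_spare),
        conventional   = .lcg_diverge(c_base, 0.25, 113L, c_spare)
      )
    ),
    A = list(
      kind = "A", template = a_base, length = 500L,
      anchor = anchor(a_base, 181L), anchor_offset = 181L, max_mismatch = 9L,
      subtypes = NULL
    ),
    T = list(
      kind = "T", template = t_base, length = 80L,
      anchor = anchor(t_base, 21L), anchor_offset = 21L, max_mismatch = 7L,
      subtypes = NULL
    ),
    TE = list(
      kind = "TE", template = te_base, length = 250L,
      anchor = anchor(te_base, 71L), anchor_offset = 71L, max_mismatch = 9L,
      subtypes = list(
        TE1 = .lcg_diverge(te_base, 0.25, 441L, te_spare),
        TE2 = .lcg_diverge(te_base, 0.25, 442L, te_spare)
      )
    )
  )
  .profile_env$profiles <- prof
  prof
}

# signature template: 34 active-site positions on the A scaffold, with the
# 10 diagnostic (substrate-pocket) positions as indices into the 34. The
# positions are shipped as data (here, a constant table) following the
# Stachelhaus convention of indexing relative to a fixed reference A domain.
.signature_positions <- list(
  idx34 = as.integer(seq(231L, by = 5L, length.out = 34L)), # 231..396
  idx10_in_34 = c(1L, 4L, 8L, 12L, 15L, 19L, 23L, 27L, 30L, 34L)
)

#' Signature template for A-domain active-site extraction
#'
#' The anchor reference A-domain scaffold together with its 34 active-site
#' template positions and the 10 diagnostic positions (indices into the 34)
#' used for substrate prediction.
#'
#' @return list with `anchor_sequence`, `idx34` (positions on the anchor) and
#'   `idx10_in_34` (strictly increasing indices in 1..34).
#' @export
signature_template <- function() {
  list(anchor_sequence = domain_profiles()$A$template,
       idx34 = .signature_positions$idx34,
       idx10_in_34 = .signature_positions$idx10_in_34)
}
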