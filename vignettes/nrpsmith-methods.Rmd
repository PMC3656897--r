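---
title: "From NRPS assembly lines to cyclic lipopeptide structures: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From NRPS assembly lines to cyclic lipopeptide structures: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nrpsmith)
```

## The inference chain

Non-ribosomal peptide synthetases (NRPSs) are multi-modular enzymes in which
each module — a condensation (C), adenylation (A) and thiolation (T) domain —
incorporates one amino acid into a growing peptide. Type-A *Pseudomonas*
lipopeptide systems obey the co-linearity rule: module order and count match
the product's residue order and count. This package implements the full
in-silico chain from NRPS protein sequences to a verifiable cyclic
lipopeptide structure:

1. **Annotation** — detect C/A/T/TE domains, group them into modules, and
   join proteins (in user-declared gene order) into an assembly line.
2. **Classification** — predict each A domain's substrate by its
   Stachelhaus signature (nearest neighbour) and by phylogenetic placement;
   type C domains as starter / dual condensation-epimerization (C/E) /
   conventional; type thioesterases as TE1 (release/cyclization) or TE2
   (editing).
3. **Product prediction** — apply co-linearity, derive D/L configuration
   from the C/E rule, enumerate macrolactonization candidates and congeners.
4. **Chemical verification** — formula algebra, monoisotopic masses and
   adduct m/z, compared against high-resolution MS evidence; NMR
   chemical-shift heuristics locate the depsi bond and call alkene geometry.

The xantholysin system (three synthetases of 2, 8 and 4 modules; a
14-residue peptide closed into an eight-residue macrolactone on Ser7;
congeners from Ile14→Val and C10:0→C12:1 fatty-acid exchange) is the worked
example threaded through the package and its tests.

## Mass arithmetic and its conventions

A residue "as incorporated" is the free amino acid minus one water. A
structure's neutral formula is

> sum of residue compositions + H₂O (chain termini)
> + fatty-acid composition − H₂O (N-acyl amide, when lipidated)
> − H₂O (macrolactone, when cyclized),

with 3-hydroxy fatty acids contributing CₙH₂ₙ₋₂dO₃ for *n* carbons and *d*
double bonds. Monoisotopic masses use IUPAC atomic masses; protonated
adducts add the **proton mass** (1.007276 Da), not the hydrogen-atom mass —
only under that convention do computed `[M+H]+` values agree with
high-resolution "expected mass" figures at 4 decimals. Reported masses are
rounded half-even at 4 decimals, the precision of such figures. Note that
papers often print *observed* ion masses in the running text; verification
should anchor to expected (theoretical) values, which this package
computes.

```{r masses}
xanA <- lipopeptide_structure(
  c("Leu","Glu","Gln","Val","Leu","Gln","Ser",
    "Val","Leu","Gln","Leu","Leu","Gln","Ile"),
  fatty_acid = fatty_acid_spec(10), lactone_donor = 7)
comp <- compose_formula(xanA)
hill_formula(comp)
adduct_mz(comp, "[M+H]+")
mass_delta_explain(14.02, tolerance = 0.05)[, 1:2]
```

Glx (Glu-or-Gln) and Xle (Leu-or-Ile) are first-class ambiguity codes:
formula composition refuses to guess and either takes an explicit
resolution or enumerates both (0.98402 Da per Glx).

## Domain detection: motif-anchored, profile-free

Detection is anchored on the field's core motifs — HHxxxDG (C), the A3
core (A), the invariant-serine T motif, GxSxG (TE) — embedded in packaged
scaffold templates. A 24-residue anchor window around each motif is
searched allowing up to 7–9 mismatches; each anchor match is extended to
the nominal domain length (C ≈ 450, A ≈ 500, T ≈ 80, TE ≈ 250 aa) and
scored by identity against the kind's template; overlaps resolve by score,
then leftmost start, then kind order. This is deterministic and needs no
external HMM database. The binomial arithmetic gives large safety margins
at the study conditions: at a 5% per-site substitution rate the probability
of losing an anchor (≥10 mismatches in 24 positions) is below 10⁻⁸, while
a random 24-mer matches with ≤9 mismatches with probability below 10⁻¹³,
so both the 100%-recall and the ≤1 false hit per 10⁴ residues targets hold
with room to spare. Users preferring profile-HMM annotation can import
third-party coordinates via `read_domain_table()`.

Boundary conventions differ between annotation tools; coordinates are
therefore validated only on synthetic ground truth, and for natural
sequences module *counts*, not coordinates, are the reproduction target.
Machine outputs are 0-based half-open with an explicit
`coordinate_system` field; human-readable reports are 1-based.

## Phylogeny: distances, NJ, and the 0.45 grouping rule

Internally the package computes p-distances (optionally Poisson-corrected,
−ln(1−p)) over gap-free column pairs and builds Saitou–Nei neighbor-joining
trees. Two deterministic refinements: Q-matrix ties break by the
lexicographically smallest label pair, and negative intermediate branch
lengths are clamped to zero with the deficit shifted to the sister branch,
preserving the joined pair's path length. Maximum-likelihood inference is
deliberately out of scope; externally built trees can be imported from
newick as the fidelity path, and placement accepts such trees directly.

Module relatedness uses **patristic distances** (summed branch lengths).
The grouping rule colours two domains alike when their patristic distance
is < 0.45. Because colours denote classes rather than pairs, the rule is
interpreted as single-linkage connected components by default; the raw
sub-threshold pairs are also exposed (`closure = "pairs"`) since the
pairwise reading is equally defensible. The 0.45 value was calibrated on
maximum-likelihood trees; under internal NJ trees the threshold's meaning
can shift, which is another reason tree import exists.

## Substrate calling and typing

`extract_signature()` globally aligns an A domain to the packaged anchor
scaffold (BLOSUM62, affine gaps open 11 / extend 1 — fixed constants for
bit-exact reproducibility) and reads the 34 active-site positions; the 10
diagnostic pocket positions are indices into the 34, shipped as data so the
convention can be corrected without code changes. Nearest-neighbour calling
scores exact identities out of 10; the confidence floor defaults to 6/10
(an implementer default — the signature literature gives none) and
co-optimal labels are always reported. Placement calling reports the label
of the patristically nearest reference, with a Δ = 0.05 ambiguity margin
(also an implementer default). An SVM-based predictor is intentionally not
embedded: its weights are not reproducible from the literature, and the
printed head-to-head disagreement (Asp vs Glu at one position) is exactly
the kind of case the placement method is meant to arbitrate.

C-domain and TE typing reuse the placement machinery against labelled
panels. Module-1 C domains are additionally marked as positional starter
candidates; a TE call that contradicts its tandem ordinal (first = TE1,
second = TE2) is flagged, never silently resolved.

## Product prediction

Stereochemistry follows the dual C/E rule: residue *i−1* is D exactly when
module *i*'s C domain is C/E; the C-terminal residue stays L. The output
carries a machine-readable `"predicted"` caveat because documented
deviations from this rule exist among natural lipopeptides.

Cyclization is **enumerated, never auto-chosen**: every internal Ser, Thr
or aThr is a candidate donor closing to the C-terminus (ring size
`n − donor + 1`). The entolysin case — pentacyclic closure through Ser10
rather than the C-proximal Ser13 — shows that any "last hydroxyl residue"
heuristic would be wrong, so selection requires user input or NMR
evidence: `flag_depsi_sites()` flags hydroxyl H-β sites whose mean
downfield deviation from random-coil shifts exceeds 0.3 ppm (default; the
observed Ser donor deviation in the xantholysin data is 0.61 ppm, and
non-donor sites sit near zero, so the threshold bisects a wide gap).
`classify_alkene_geometry()` calls cis/trans from the sign of the flanking
allylic ¹³C shift changes relative to the saturated analog (steric
compression shifts both upfield in cis).

Congener enumeration takes the Cartesian product of per-position residue
choices and fatty-acid variants; for mass rendering Glx must be resolved
explicitly (the pipeline default resolves Glx→Gln, Xle→Leu, and isoform
masses can be enumerated separately).

## The synthetic-data generator

Real reference signatures and domain boundaries are not redistributable in
bulk, so every stage is exercised against a seeded generator that emulates
the architecture of multi-modular lipopeptide synthetases: ordered C–A–T
modules with planted motifs, class-specific signature residues (classes
differ at ≥ 6/10 pocket positions by construction), C-subtype and TE1/TE2
variant scaffolds (25% divergence outside the anchor regions), random
10–60 aa linkers rejection-sampled to exclude core motifs, and a terminal
TE tandem. Scaffolds come from an internal linear congruential generator,
so the packaged profiles are platform-independent constants; all other
randomness flows from a single user seed, and generator calls restore the
caller's RNG state.

Default study conditions: a 2/8/4-module three-protein line (the
xantholysin architecture), 5% per-site query mutation (panels at 5%
reference divergence), 10% mutation for classifier stress tests with 200
seeded queries. What the generator does **not** emulate: indel evolution
(beyond planted insertions), rate heterogeneity, compositional bias, and
the real divergence structure of natural A-domain families. Passing
synthetic tests therefore demonstrates the machinery's correctness and
calibration, not its accuracy on natural sequences — for those, module
counts and imported-tree placement are the validated path.

## Numerical and degenerate-input choices

* Masses round half-even at 4 decimals; equality tests on masses use
  1 × 10⁻⁴ Da.
* Saturated pairs under Poisson correction (p ≥ 1) are an error naming the
  pair, as is a pair with zero comparable columns.
* NJ needs ≥ 3 taxa; 3-taxon trees use the closed-form solution implicitly.
* Scan hits below an identity score of 0.3 against the best template are
  dropped (random windows score ≈ 0.05, planted domains ≥ 0.65).
* An empty hit list yields "no modules" diagnostics, never a silent empty
  line; orphan hits that fit no complete C-A-T cassette are always listed.
* Signature extraction refuses alignments covering < 60% of the template.

## Problem sizes used in the shipped tests

The test suite runs the mass identities over 25 random structures, the
patristic oracle over 100 random trees (4–20 tips), NJ recovery over 50
seeded additive quartets cycling the three labelled topologies, substrate
NN accuracy over 200 seeded queries at 10% mutation, C and TE typing over
100 queries each, the stereo rule over 50 random subtype plans, and full
pipeline determinism on a compact two-module line. These sizes were chosen
to estimate the relevant rates stably while keeping the suite quick on a
laptop.

## Known limitations

* Real-sequence reproduction (module counts 2/8/4, C typing 1 starter /
  11 C/E / 2 conventional, ~70.5% XtlABC-vs-EtlABC identity) requires the
  GenBank translations, which must be fetched by the user
  (`inst/cli/fetch_real_inputs.R`); the corresponding check reports a
  failure until those inputs are present.
* Stereochemistry output is a prediction; the xantholysin stereochemistry
  itself was never determined experimentally beyond "mostly D".
* Whether A-domain "switches" between congener families should be modelled
  as congeners is left open (the MA026 case); the congener enumerator only
  varies per-position alternatives and fatty acids.
* No isotope patterns, MS/MS fragmentation, retention-time or 3D modelling.
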