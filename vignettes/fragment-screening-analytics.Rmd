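---
title: "Fragment-screening analytics: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Fragment-screening analytics: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fragsite)
```

`fragsite` implements the computational stages of a biophysical
fragment-screening campaign: geometric binding-site definition,
site-versus-global ortholog conservation, CPMG NMR hit calling with
competition, one-set-of-sites ITC simulation and fitting with
ligand-efficiency derivation, and backbone superposition. This vignette
is the package's account of the underlying models, the parameters that
matter, the numerical choices made where the design was genuinely open,
and what the synthetic-data generators do and do not emulate.

## Binding-site definition from coordinates

A binding site is operationally the set of *k* protein residues closest
to a bound ligand. For each protein residue we take the minimum
heavy-atom-to-heavy-atom Euclidean distance to the ligand's heavy atoms
and keep the *k* smallest (default *k* = 20, a size that in practice
spans the first and second contact shells of a fragment-sized ligand).
The companion convention, `contact_residues()`, keeps every residue
within a fixed cutoff instead (default 4 Å, the usual crystallographic
contact-shell radius); it always returns a prefix of the full
distance-sorted residue table, so the two definitions are mutually
consistent by construction.

Choices a reader should know about:

* **Heavy atoms only, both sides.** Crystal structures at typical
  fragment-screening resolution carry no hydrogens, and adding them
  would make the definition model-dependent. Waters (`HOH`) and other
  hetero residues are excluded from the protein side.
* **One chain at a time.** Crystals with two protein copies in the
  asymmetric unit would otherwise mix residues from both molecules into
  one "site". The default chain is that of the protein atom nearest the
  ligand; `chain` overrides it. Which copy (and which ligand pose) to
  use is exposed rather than hard-coded, since either copy is a
  defensible choice.
* **Deterministic ties.** Residues tied at the cut rank are ordered by
  (chain, residue number), so repeated runs agree byte for byte.
* **Altloc resolution.** Alternate conformers collapse to the
  highest-occupancy one; occupancy ties prefer altloc `A`, then first
  occurrence. Author residue numbering is kept as printed — no
  renumbering.

## Site-versus-global conservation

Given an aligned FASTA of orthologs and a reference sequence, percent
identity is computed **reference-anchored**: the denominator is the set
of alignment columns where the reference is non-gap (optionally
intersected with a site's columns), and an ortholog gap in a counted
column scores as a mismatch. This rule follows directly from sites being
defined as reference residue numbers: every site position is always a
counted column, for every ortholog, so site identities are comparable
across orthologs. The alternative rule — dropping ortholog-gap columns
from the denominator, as pairwise-identity tools often do — is available
via `gap_rule = "pairwise"`; on closely related ortholog sets the two
differ by at most a few percent. `X` never matches anything, including
itself; matching is case-insensitive. An identity over zero counted
columns is an error, never silently 0.

Structure residue numbers are assumed to be the reference's ungapped
positions (UniProt-style numbering). For engineered constructs whose
numbering is shifted — e.g. an N-terminally truncated protein whose
first residue is 36 — `site_definition(..., offset = 35)` converts
construct numbering to reference positions.

A site plotted above the identity diagonal
(`plot(conservation_profile(...))`) is more conserved than the protein's
background, the standard sequence-based argument that a pocket of
unknown function is functionally constrained.

## CPMG hit calling and competition

Ligand-observed CPMG screening reports, per fragment, the signal
intensity without protein (`i_ref`), with protein (`i_protein`), and
optionally after adding a competitor ligand of a known site
(`i_competitor`). The attenuation ratio `rho = i_protein / i_ref` is
scale-free; binding accelerates transverse relaxation and drives `rho`
below 1.

* **Binder threshold.** `rho <= tau` calls a binder, boundary included.
  `tau` defaults to 0.8 — at least 20 % attenuation, standard practice
  for a 600 ms CPMG train — but screening cutoffs are lab-specific, so
  `tau` is an explicit parameter everywhere and never buried.
* **Competition.** If the competitor displaces the fragment from its
  site, the fragment tumbles freely again and its signal recovers toward
  the reference. We call `site1_competed` when
  `rho_comp - rho >= recovery_delta` (default 0.15); binders without a
  competitor measurement, and all non-binders, are `not_tested`. The
  recovery threshold is likewise an explicit parameter: published
  screens rarely state a numeric criterion.
* **One row per fragment.** Input tables are pre-aggregated over a
  fragment's resonances (minimum-ratio convention); raw spectrum
  processing is out of scope.

The summary hit rate is `100 * n_hits / n_library` rounded to one
decimal, matching how screening campaigns report it.

## The one-set-of-sites ITC model

For a single class of `n` identical, independent sites, the fractional
saturation Θ at total macromolecule `M_t` and total ligand `X_t` solves
the binding quadratic; the closed form is

    Θ = ½ [ 1 + X/(nM) + 1/(n·Ka·M) − sqrt( (1 + X/(nM) + 1/(n·Ka·M))² − 4X/(nM) ) ]

and the cumulative heat content of the cell is
`Q = n · Θ · M_t · ΔH · V0`. Θ is clamped to [0, 1]; a negative
discriminant (impossible for valid inputs, possible under floating-point
cancellation) is clamped to zero with a warning. The tests verify Θ
against an independent root-finder on the same quadratic.

**Dilution bookkeeping.** Each injection of volume `v` into a
constant-volume cell displaces well-mixed contents: concentrations
update as `M → M(1 − v/V0)` and `X → X(1 − v/V0) + X_syr·(v/V0)`, and
the measured heat of injection *i* includes the half-volume correction

    q_i = Q_i − Q_{i−1} + (v_i/V0) · (Q_i + Q_{i−1})/2 + q_dil.

Commercial instrument software is not explicit about its exact
convention; ours is self-consistent, and because the fitter uses the
same forward model as the simulator, parameter recovery is
convention-independent — which is also the property the tests assert.

**Fitting.** `fit_one_set_of_sites()` minimises least squares over
(n, log10 Ka, ΔH, q_dil) with Levenberg–Marquardt. Fitting Ka on a log
scale keeps the step size meaningful across the µM-to-nM range; starts
for ΔH come from the stoichiometric first-injection limit
(`ΔH ≈ q_1 / (X_1 V0)`), and a log-spaced grid of Ka starts (c = 1, 10,
100, 1000) guards against the isotherm's flat directions — the best
converged start by SSE wins. Non-convergence is reported as
`converged = FALSE`, never silently. The dilution offset `q_dil` is a
fitted constant by default; after buffer-control subtraction it can be
fixed at 0 (`fit_dilution = FALSE`). A `discard_first` flag implements
the common first-injection discard; the default keeps it. The fit warns
when the Wiseman c-value `n·M0/Kd` leaves the reliable window of about
1–1000, where n, Ka and ΔH decorrelate poorly.

**Derived thermodynamics.** `ΔG = R·T·ln Kd` with
`R = 1.9872e-3 kcal/(mol·K)`, natural log, `T` defaulting to 298.15 K;
`−TΔS = ΔG − ΔH`. Ligand efficiency `LE = −ΔG / N_heavy` is reported at
full precision alongside a 2-decimal presentation column, the rounding
used in compound tables. Heavy-atom counts are user inputs — the package
does no structure perception.

## Dose–response (EC50)

`fit_4pl()` fits the four-parameter logistic on log10 concentration via
the self-starting `SSfpl` model, reparameterised to (bottom, top, EC50,
Hill). Noise-free data defeat `nls`'s relative-offset convergence test,
so the fit uses `scaleOffset = 1` with a Levenberg–Marquardt fallback.
Flat curves return `ec50 = NA` with `converged = FALSE` rather than an
error; an EC50 outside the tested range, or a residual scale rivalling
the response range, is flagged with a warning, not a failure.

## Backbone superposition

`superpose_backbone()` pairs residues by (chain, residue number) —
or an explicit pairing table — takes the four backbone atoms
{N, CA, C, O} per residue, and computes the least-squares rigid
superposition by the Kabsch/SVD construction with reflections excluded
(determinant forced to +1). Residues missing any backbone atom in either
model are dropped from the pairing with a warning; fewer than three
complete pairs is an error. Rank-deficient (e.g. collinear) point sets
are flagged `degenerate`: the rotation about the degenerate axis is
arbitrary but still proper. The tests check the analytic RMSD against a
general-purpose numeric optimiser over rigid motions and against an
established structural-bioinformatics fitter.

## What the synthetic generators emulate

The generators define the package's study conditions; their defaults
were fixed once, on the following reasoning, and are not tuned.

* **Ortholog families** (`generate_ortholog_family()`): reference length
  217 (a typical cap-binding initiation-factor length), 30 orthologs,
  per-position substitution probability 0.12 outside the site and 0.02
  inside — the identity range of mammal-to-vertebrate ortholog sets —
  with substitutions uniform over the 19 alternative residues and indel
  probability 0 by default. This emulates exactly what the conservation
  stage consumes: a columnar alignment whose site columns are enriched
  for identity. It does **not** emulate phylogenetic correlation between
  orthologs, rate variation beyond the two-class site/background split,
  substitution-matrix realism, or indel-rich alignments — so passing
  tests demonstrate correct identity arithmetic and site mapping, not
  evolutionary realism.
* **Screening decks** (`generate_screen_deck()`): 1371 fragments in
  cocktails of four, 50 planted binders — a 3.6 % hit rate, typical of a
  fragment screen against a ligandable target — with binder ratios drawn
  below `tau − margin` and non-binders above `tau + margin`
  (margin 0.05), and 20 % of binders competable at the primary site
  (fragment screens typically find a minority of hits in a known
  orthosteric site). The margin makes planted truth recoverable exactly;
  real decks have borderline fragments, so perfect sensitivity here says
  nothing about borderline behaviour.
* **Titrations**: the simulator is the fitted model plus Gaussian heat
  noise — it does not emulate baseline drift, injection artefacts, or
  active-site titration errors. Recovery tests therefore measure the
  estimator's statistical behaviour, not robustness to instrument
  systematics.
* **Toy structures** (`generate_toy_structure()`): line, helix or
  random-sphere residue layouts with a rigid local backbone and one
  hetero ligand, emitting the true residue–ligand distance table
  alongside the PDB text so geometric tests compare against generator
  truth, never against a re-derivation.

All generators are pure functions of their arguments and seed;
re-running one reproduces its output byte for byte.

## Problem sizes used in validation

The test-suite and acceptance computations use deliberately desk-scale
problems: 100 random toy structures for the brute-force site property,
20-seed ortholog-family sweeps, a 1371-fragment deck, and 20 replicate
17-injection titrations at c ≈ 110 with 1 % heat noise for parameter
recovery (median fitted Kd and n). These sizes give stable medians while
keeping a full validation run in well under a minute per stage.

## Known limitations

* PDB fixed-column input only; mmCIF is not parsed.
* Single-site ITC only: no competitive, sequential or multi-site models,
  and no integration of raw power traces.
* Conservation is strict identity — no similarity scoring, no
  phylogenetic weighting.
* The pipeline runner executes tasks sequentially in config order; task
  blocks do not declare inter-task dependencies beyond file paths.
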