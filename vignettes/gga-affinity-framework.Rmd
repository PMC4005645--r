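---
title: "Predicting CsrA/RsmE binding affinity from GGA motif context"
author: "ggaffinity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting CsrA/RsmE binding affinity from GGA motif context}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ggaffinity)
```

## The biological problem

Carbon-storage-regulator proteins of the CsrA/RsmE family are homodimeric
translational repressors that clamp onto GGA trinucleotides in mRNA 5'-UTRs,
typically occluding the ribosome binding site (RBS). Small regulatory RNAs
such as RsmZ, RsmY and RsmX carry many GGA motifs and act as decoys: they
titrate the protein away from mRNAs, de-repressing translation. The same
protein binds different GGA motifs with dissociation constants spread over
more than five orders of magnitude — roughly 10 nM for a canonical hexaloop
element down to about 3 mM for a motif buried inside a helix — and that
spread, not any sequence-specific side-chain readout, is what tunes the
competition between mRNAs and sRNAs.

This package implements the affinity-prediction framework that maps a GGA
motif's sequence and secondary-structure context onto a dissociation-constant
tier, together with the measurement models behind such numbers (isothermal
titration calorimetry and slow-exchange NMR) and an equilibrium
sequestration model that turns per-motif affinities into predictions about
translation repression and de-repression.

## The context classification

A motif is read against the consensus element **A**(N)**GGA**X: an anchor
adenine, an optional looped-out nucleotide N, the invariant GGA core, and a
variable 3' nucleotide X. Classification is purely geometric and proceeds in
two stages:

1. **Pairing state first.** If all three G,G,A bases sit in a helix the
   motif is `FULLY_PAIRED`; if one or two do, `PARTIALLY_PAIRED`. Binding
   then requires disrupting the helix, which costs the most affinity.
2. **Loop geometry second.** For an unpaired motif we look at the maximal
   unpaired run containing it. If that run is a hairpin loop sitting on a
   stem of at least two stacked pairs, the loop register decides:
   `A N G G A X` filling a 6-nt loop is the canonical `HEXALOOP_ON_STEM`;
   a 5-nt `A R G G A` loop with purine R is `PURINE_PENTALOOP`; a 5-nt
   `A G G A X` loop (N missing) is `PENTALOOP_NO_N`; any other
   motif-containing loop is `EXPANDED_LOOP` with the count of nucleotides
   inserted between the element and the stem. Unpaired motifs without an
   adequate closing stem — exterior regions, internal loops, bulges, or
   loops on a single closing pair — are `SINGLE_STRANDED`.

"On top of a stem" is not defined quantitatively anywhere; we require at
least two contiguous stacked pairs below the loop, because the measured
high-affinity constructs all close with two defined pairs (C-G under the
loop, then U-A) and a single isolated pair is not a stable stem at assay
temperatures. Loops on a single pair are classified single-stranded and
flagged `loop_on_single_pair_stem`.

The identities of the closing and penultimate pairs are recorded as features
but do not move the tier: the protein recognizes the stem semi-specifically
through adaptable side-chain contacts, so any Watson-Crick closing pair
supports the same geometry.

## Tier calibration

Tiers map contexts to dissociation-constant ranges:

| tier | Kd range (M) | exemplar contexts |
|---|---|---|
| HIGH | 5e-9 – 5e-7 | hexaloop on stem; purine pentaloop |
| INTERMEDIATE | 5e-7 – 1e-5 | pentaloop without N; expanded loop; single-stranded |
| INTERMEDIATE_LOW | 1e-5 – 1e-4 | heavily expanded loops (>4 inserts) |
| LOW | 1e-4 – 1e-3 | 1–2 of G,G,A base-paired |
| VERY_LOW | 1e-3 – 1e-2 | GGA fully base-paired |

The measured reference points only establish groupings and exemplar values,
not boundaries; these bounds were chosen once so that every packaged
reference constant falls inside its tier, the tiers are disjoint and
ordered, and the whole ladder spans the observed five decades. They are
returned by `tier_table()` and a point value per tier (the geometric mean of
its range) by `tier_kd()`.

Two deliberate judgement calls:

* An unpaired motif lacking the anchor adenine is demoted one tier — the
  anchor contributes conserved backbone hydrogen bonds. No demotion applies
  to base-paired motifs, whose tier already prices the helix disruption.
* A single-stranded motif missing N keeps the intermediate tier rather than
  being demoted: in the single-stranded benchmark the ribose backbone
  substitutes for the looped-out nucleotide and the affinity barely moves.
  The report flags this (`n_absent_ss_backbone_compensated`).
* Expanded loops with more than four inserted nucleotides are beyond any
  measured construct; they drop to INTERMEDIATE_LOW and are flagged
  `insertion_count_extrapolated`.

Overlapping GGA windows (G-runs) are deduplicated by the anchor rule:
within a group of mutually overlapping windows the register that forms a
canonical loop element wins, then a register with an anchor A, then the
leftmost. `scan_motifs()` reports both the deduplicated motifs and the raw
window count.

## Calorimetry model

`itc_isotherm()` is a forward model of a perfusion calorimeter: injecting
volume `v` into the cell (volume `V0`) dilutes the pre-existing content by
`V0/(V0+v)`, the expelled liquid carries complex at its pre-injection
composition, and the measured heat of injection `i` is

```
q_i = V0 * ( [PL]_i dH1 + [PL2]_i (dH1 + dH2)
           - d_i ( [PL]_{i-1} dH1 + [PL2]_{i-1} (dH1 + dH2) ) ) + q_dil
```

with `d_i = V0/(V0+v_i)`. Species concentrations come from the exact mass
balance: a stable quadratic for the one-site model and the closed-form cubic
for the sequential two-site model (macroscopic constants `Kd1 <= Kd2` for
the first and second ligand binding the homodimer), each polished by Newton
iteration to a relative residual below 1e-12. The two binding events are
kept macroscopic throughout; no statistical-factor conversion is applied,
matching how two-site calorimetry fits are conventionally reported.

`fit_itc()` minimizes squared residuals with Levenberg-Marquardt over
`log10(Kd)`, the enthalpies and the dilution offset, from eight multi-starts
on a log-spaced Kd grid with seeded jitter (gradient/step tolerances 1e-12).
The stoichiometry correction `n` multiplies the cell protein concentration
and is fixed at 1 unless freed — with concentrations determined
spectrophotometrically after dialysis the active fraction is near one, and
freeing `n` on a two-site model invites parameter trade-off. Standard
errors come from the finite-difference Jacobian at the optimum; `dG = RT ln
Kd` and `TdS = dH - dG` are evaluated at the experiment temperature
(default 298 K, R = 8.314 J/mol/K).

## Slow-exchange NMR estimator

When complex dissociation is slow on the chemical-shift timescale, free and
bound species give separate resonances and their integrals measure the bound
fraction directly. For each resonance pair,

```
f = I_bound / (I_free + I_bound),   c = f * min(Ptot, Rtot),
Kd = (Ptot - c)(Rtot - c) / c
```

aggregated as an unweighted mean ± sample standard deviation across pairs.
The general quadratic form handles unequal totals, although the benchmark
titrations used equal 0.54 mM totals. `bound_fraction_forward()` is the
exact inverse (the stable root of the mass-balance quadratic), so
noise-free simulation and estimation round-trip to machine precision —
which is how the packaged 300 µM and 2.7 mM reference constants are
reproduced in the acceptance checks. Bound fractions of exactly 0 or 1 are
outside the quantifiable range and raise an error.

## Sequestration model

The competition model treats every GGA motif as an independent ligand for
identical protein sites, two per homodimer. Free sites `S` solve

```
S + sum_j M_j * S / (Kd_j + S) = S_tot
```

(monotone, bracketed root, Newton-polished to a 1e-12 relative residual);
per-pool occupancy is `S/(Kd_j+S)`. Translation activity is `1 - theta_RBS`
normalized to the maximum over the evaluated grid, mirroring reporter
assays that normalize to the fully de-repressed signal; absolute expression
units are not modelled.

The model deliberately stops at per-motif constants: one dimer bridging two
motifs on the same RNA (as the first dimer does across the two tight hcnA
sites) is represented only as "both tight sites fill first", not as an
explicit avidity term, because the framework supplies no bridging
parameters. Likewise kinetics (all these complexes dissociate slowly,
<10/s) and RNA lifetime effects are out of scope; everything is equilibrium.

Scenario presets use 100 nM protein dimer (the cell-free assay
concentration); the 6–17 µM cellular range can be passed explicitly. Sites
known only by tier enter with the tier's geometric-mean constant.

## Synthetic data

The generators emulate the benchmark constructs, not real transcriptomes:

* `make_rna_with_motif()` builds hairpins with complementary Watson-Crick
  stems (60% GC, closing C-G over U-A like the measured stem-loops), plants
  one A(N)GGA(X) element per record, and draws unpaired filler from
  {A, C, U} so no spurious GGA can appear in filler. Real sRNAs have
  multiple motifs, wobble pairs, bulged stems and alternative structures;
  passing the planted-class recovery suite therefore shows the classifier
  implements its definition exactly, not that real structures are always
  classified as a biologist would.
* `make_itc()` adds additive Gaussian noise to the forward isotherm
  (instrument-like); `make_integral_pairs()` applies multiplicative
  lognormal noise per peak (integration-like). Neither noise model is
  measured from instruments; both are configurable.
* The `sl2_itc` preset uses the packaged two-site reference constants
  (16 nM, 185 nM) with enthalpies of -90 and -70 kJ/mol and a -0.5 µJ
  dilution offset. The enthalpies are this package's own realistic choice
  for a high-affinity protein-RNA interaction with the first event more
  exothermic; only the relative ordering, not the values, is established by
  the calorimetric record.

All generators are pure functions of (spec, seed) and restore the caller's
RNG state.

## Problem sizes and numerical choices

The packaged simulation study fits 50 two-site thermograms of 35 injections
each (8 µl of 300 µM RNA into 1.4 ml of 10 µM dimer, 1% full-scale noise) —
at the first constant this design has a Wiseman c-value of about 600, so
individual fits scatter noticeably and the study reports medians, which land
within the ±3 nM printed uncertainties of both constants. Classifier
validation uses 500 randomized geometries per context class. Root solving
is closed-form wherever possible (quadratic/cubic) with Newton polish;
`uniroot` bracketing is the fallback. Ties in knockout rankings are kept in
input order and reported, not broken arbitrarily.

## Known limitations

* Structure is an input; the package does not fold RNA. The optional
  command-line `--fold` hook is disabled by default and never used in tests.
* Pseudoknots, IUPAC ambiguity codes and DNA alphabets are rejected rather
  than guessed at.
* Tier boundaries are calibrated to one protein family (CsrA/RsmE-type
  dimers); other RNA-binding proteins need their own calibration.
* No global multi-experiment ITC fitting, no raw power-trace integration or
  baseline correction — inputs are integrated heats.
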