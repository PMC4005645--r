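# ggaffinity

Predicting CsrA/RsmE binding affinity of RNA GGA motifs from sequence and
secondary-structure context — plus the binding-thermodynamics machinery
(ITC, slow-exchange NMR) and equilibrium sequestration modelling that turn
per-motif affinities into translation repression/de-repression predictions.

## The problem

CsrA/RsmE-family proteins are homodimeric bacterial translation repressors.
Each dimer carries two identical RNA-binding sites that clamp onto GGA
trinucleotides, usually at or near the ribosome binding site (RBS) of target
mRNAs; decoy sRNAs (RsmZ, RsmY, RsmX) carry several GGA motifs and
sequester the protein, de-repressing translation. The same protein binds
different GGA motifs with dissociation constants from ~10 nM to ~3 mM —
more than five orders of magnitude — and the spread is governed by the
motif's context, read against the consensus element **A**(N)**GGA**X:

| context of the GGA | predicted tier | K_d range |
|---|---|---|
| ANGGAX hexaloop directly on a stem | HIGH | 5 nM – 0.5 µM |
| ARGGA purine pentaloop | HIGH | 5 nM – 0.5 µM |
| AGGAX pentaloop (N missing) | INTERMEDIATE | 0.5 – 10 µM |
| loop with nucleotides inserted before the stem | INTERMEDIATE | 0.5 – 10 µM |
| single-stranded, no stem | INTERMEDIATE | 0.5 – 10 µM |
| 1–2 of G,G,A base-paired | LOW | 0.1 – 1 mM |
| GGA fully base-paired | VERY_LOW | 1 – 10 mM |

The package classifies motifs into these contexts from Vienna dot-bracket
input, assigns tiers, and ships the measured reference constants used for
calibration. Around that core it provides:

* a forward model and Levenberg–Marquardt fitter for one-site and
  sequential two-site ITC isotherms (macroscopic K_d1, K_d2 of the first
  and second RNA binding the dimer), with ΔG/ΔH/TΔS decomposition;
* the slow-exchange NMR estimator
  `K_d = (P_tot − c)(R_tot − c)/c`, `c = f_bound · min(P_tot, R_tot)`,
  from free/bound peak-integral pairs;
* an equilibrium sequestration solver
  (`S + Σ M_j S/(K_dj + S) = S_tot`) for competition between an mRNA RBS
  and decoy sRNA motifs, with de-repression curves, mutant rankings and
  sequential-occupancy titrations;
* seeded synthetic generators (structured RNAs with planted motifs, noisy
  thermograms, integral pairs) so everything is testable without external
  data.

## Worked example

```r
library(ggaffinity)

# scan a hairpin with a planted ACGGAU hexaloop
fx <- fixture_preset("sl2_like")
fx$molecule
#> <rna_molecule> hexaloop_on_stem_s1 (20 nt, 4 base pairs)
#>  UACGCUCACGGAUGAGCAUU
#>  ...((((......))))...
motif_report_table(scan_motifs(fx$molecule))[, 1:7]
#>                  name start end          context tier kd_lower kd_upper
#> 1 hexaloop_on_stem_s1    10  12 HEXALOOP_ON_STEM HIGH    5e-09    5e-07
```

The motif at positions 10–12 (1-based) sits in a 6-nt ANGGAX loop on a
4-pair stem: the high-affinity context, K_d expected between 5 nM and
0.5 µM.

```r
# fit a simulated two-site titration (16 nM / 185 nM reference constants,
# 35 x 8 ul of 300 uM RNA into 1.4 ml of 10 uM dimer, 1% noise)
sl2 <- fixture_preset("sl2_itc")
e <- make_itc(sl2$params, sl2$design, noise_frac = 0.01, seed = 1)
fit_itc(e, "two_site", seed = 1)
#> <binding_fit> two_site
#>   Kd1 = 2.311e-08 M (dG1 = -43.56 kJ/mol, dH1 = -90.68, TdS1 = -47.12)
#>   Kd2 = 2.074e-07 M (dG2 = -38.13 kJ/mol, dH2 = -69.50, TdS2 = -31.38)
#>   rss = 1.18e-10, 35 injections

# slow-exchange NMR estimate at 0.54 mM totals (buried-motif scale)
kd_from_integrals(make_integral_pairs(2.7e-3, 5.4e-4, 5.4e-4, n_pairs = 6),
                  5.4e-4, 5.4e-4)
#> <kd_estimate> Kd = 0.0027 +/- 0 M (6 resonance pairs)
```

A single fit at this steep design scatters around the true constants
(here 23 nM / 207 nM against 16 nM / 185 nM generated); the packaged
simulation study below uses the median of 50 fits. The noise-free NMR
round trip returns the generating 2.7 mM exactly.

```r
# six-motif decoy sRNA (1 high, 2 intermediate, 3 low sites) vs an RBS,
# 100 nM dimer, 200 nM sRNA: which site knockout hurts de-repression most?
decoys <- list(
  ligand_pool("high1", tier = "HIGH",        site_conc = 1, role = "decoy"),
  ligand_pool("int1",  tier = "INTERMEDIATE", site_conc = 1, role = "decoy"),
  ligand_pool("int2",  tier = "INTERMEDIATE", site_conc = 1, role = "decoy"),
  ligand_pool("low1",  tier = "LOW",          site_conc = 1, role = "decoy"),
  ligand_pool("low2",  tier = "LOW",          site_conc = 1, role = "decoy"),
  ligand_pool("low3",  tier = "LOW",          site_conc = 1, role = "decoy"))
rbs <- ligand_pool("hcnA-RBS", kd = 1e-8, site_conc = 1e-8, role = "rbs")
rank_mutants(rbs, decoys, c("high1", "int1", "low1"),
             srna_conc = 2e-7, protein_dimer_conc = 1e-7)
#>   scenario activity_raw  activity
#> 1       wt   0.13164214 1.0000000
#> 4     low1   0.13160472 0.9997157
#> 3     int1   0.12642139 0.9603413
#> 2    high1   0.05777708 0.4388950
```

Knocking out the single high-affinity decoy site halves translation
activation; removing an intermediate site costs ~4%; removing a low site is
nearly neutral — the experimentally observed ordering.

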