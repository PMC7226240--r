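---
title: "Methods: time-course proteomics of the tick sialome and cementome"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: time-course proteomics of the tick sialome and cementome}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cementome)
```

## The analysis problem

Ixodid ticks anchor their mouthparts to host skin with cement, a secreted
protein polymer. Label-free (SWATH-type) quantitative proteomics of the
salivary-gland proteome (*sialome*) and the cement-cone proteome
(*cementome*) across three adult female feeding stages — T1 (shortly after
the molt to adult), T2 (secondary cement production) and T3 (just before
detachment) — yields a protein × run abundance matrix in Total Area Sums
(TAS) units, with cement proteins extracted in two buffers (SDS and urea)
and each tissue measured in biological × technical replicates. The package
implements the downstream analysis of such a design: normalization,
time-course differential representation, profile-based assignment of
proteins to developmental processes, host/tick origin and tissue partition
arithmetic, a compositional co-occurrence network, sequence-derived
physicochemical characterization, SEM–EDS elemental statistics, and α-Gal
ELISA quantitation — together with a synthetic-data generator that provides
ground truth for end-to-end validation.

## Quantitation model and differential testing

**Normalization.** `tas_normalize()` rescales each run so its total equals
the grand mean of the raw run totals. Any common target constant preserves
within-run proportions; the grand mean is fixed for reproducibility. The
operation is idempotent and leaves already-balanced matrices unchanged.

A caveat worth stating explicitly: total-signal normalization assumes the
summed abundance per run is biologically constant, so that differences in
run totals reflect instrument loading. When a large fraction of proteins
genuinely changes between time points, forcing totals equal transfers part
of that change onto unchanged proteins (closure bias). The synthetic
generator does not simulate loading variation, so its output is already on
a common scale and the validation experiments below classify the generated
matrix directly.

**Differential representation.** For each protein and each pairwise
comparison of feeding stages (T1 vs T2, T2 vs T3, T1 vs T3),
`differential_test()` applies a two-sided pooled-variance Student's t-test
at α = 0.05 with no multiple-testing correction across the three
comparisons (an optional Benjamini–Hochberg flag exists but is off by
default, matching the raw p < 0.05 convention). The default observation
unit is the run — all biological × technical replicates, n = 6 per group
under the default design — which matches testing "across the replicate
runs". `replicate_unit = "bio_rep_mean"` first averages technical
replicates within each biological replicate; this is the conservative
choice when technical replicates are strongly correlated, at the price of
2 observations per group. Proteins with fewer than two observations in a
group are flagged untestable rather than dropped, and identical groups
report t = 0, p = 1.

## Profile classification

Each protein's three comparisons reduce to a significance/direction triple
over {up, down, ns}. `profile_templates()` maps all 27 triples to one of
eight developmental-process categories. The published profile shapes are
graphical only, so the default table is an explicit reconstruction; the
design constraints were that (i) every category owns at least one exact
triple realizable by a noiseless mean trajectory, making the
generator–classifier loop closed, and (ii) the exact triples are mutually
distinct so that recovery is well defined:

| category | exact triples | trajectory shape |
|---|---|---|
| housekeeping | (ns, ns, ns) | flat |
| molting | (down, down, down), (down, ns, down) | decline from a T1 high |
| secondary cement production I | (up, down, up), (up, down, ns) | T2 peak, retained above baseline |
| secondary cement production II | (up, down, down) | transient T2 burst |
| cement maintenance | (ns, down, down) | early high held through T2 |
| feeding | (up, up, up) | monotone rise |
| feeding and oogenesis | (ns, up, up), (ns, ns, up) | late rise |
| detachment | (down, up, up) | suppressed mid-feeding, T3 spike |

The 16 remaining triples are filled by Hamming-nearest assignment with a
fixed priority order (molting > secondary I > secondary II > maintenance >
feeding > feeding and oogenesis > detachment). Housekeeping is matched
exactly only: one significant comparison anywhere makes a protein
"differentially represented". The table ships as an editable data frame
and survives a JSON round-trip (`write_templates()` / `read_templates()`),
so an alternative reading of the profile shapes is a configuration change,
not a code change.

An intentionally asserted consequence of the raw-α gate: under a pure
null, a protein escapes housekeeping whenever any of the three dependent
t-tests fires. Because the comparisons share groups, the escape
probability is below the independence value 1 − (1 − α)³ = 0.1426; direct
Monte-Carlo simulation of three pooled t-tests on shared Gaussian groups
of six gives 0.123 (se 7 × 10⁻⁴), and `null_calibration_experiment()` is
tested against that number.

## The synthetic-data generator

`generate_dataset()` draws protein abundances log-normally around
category-specific mean trajectories. For protein *i* in run *(tissue,
time, bio, tech)*:

log A = baseline*ᵢ* + log(effect_size) · template(category*ᵢ*, time) +
biological effect + technical noise,

with per-protein baselines N(log 10⁵, 1), multiplicative noise expressed
as coefficients of variation (`cv_technical`, `cv_biological`, both 0.1 by
default; log-scale sd = √log(1 + cv²)), and the biological effect shared
by all technical replicates of a (tissue, time, biological replicate)
cell, including the two cement extractions of the same material. The
default design is 3 sample types × 3 stages × 2 biological × 3 technical
replicates = 54 runs. `effect_size` ≥ 1 is accepted so the degenerate
value 1 can drive pure-null calibration runs. Tissue membership
(sialome-only / cementome-only / shared) zeroes a protein out of the other
tissue's runs; host proteins draw their category from a separate weight
vector that concentrates 86% of them in feeding-and-oogenesis plus the two
secondary-cement categories, mirroring the dominance of those profiles
among host-derived proteins; tick proteins default to equal weights over
the eight categories. A configurable fraction of tick proteins receives
Gly-biased sequences (target Gly mole fraction uniform in 30–45%, the
range reported for cement-like structural proteins); everything else draws
residues uniformly.

What the generator does *not* emulate: peptide-level quantitation and
roll-up, missing-value structure from detection limits, run-loading
variation, correlated protein modules beyond the planted SparCC tests, and
realistic sequence phylogeny. Passing the recovery experiments therefore
demonstrates correctness of the statistical machinery under the stated
noise model, not robustness to everything real SWATH data can do.

**Validation experiments.** `recovery_experiment()` (defaults: 200
proteins, effect size 4, one multiplicative noise level cv = 0.1 at the
technical layer, runs as observations) recovers ≥ 95% of true categories;
the acceptance suite asserts this at a fixed seed. The expected ceiling is
informative: housekeeping is recovered with probability 0.95³ ≈ 0.857
(three chances for a false positive), categories whose exact triple
contains one `ns` state with ≈ 0.95, and fully-significant categories with
≈ 1, giving ≈ 0.97 overall at equal weights. `null_calibration_experiment()`
(effect size 1) reproduces the 0.123 non-housekeeping rate above.

## Partition arithmetic and key-protein selection

`build_partition()` forms the cementome as the exact-accession union of
the SDS and urea cement identifications and counts, per origin, the
sialome-only / cementome-only / shared cells. Accessions are opaque
strings; no protein-group merging is attempted. The published worked
example — 388 SDS + 266 urea = 654 union (the printed sets are disjoint),
62 shared proteins of which 13 tick and 49 host, and 13 + 68 = 81 tick
cementome proteins — is reproduced exactly by the acceptance suite from
the printed component counts.

`select_key_proteins()` scores four criteria per protein: shared between
sialome and cementome; among the top 2 by mean normalized TAS within its
(non-housekeeping) profile category, boundary ties all kept; annotated to
a GO biological process holding > 4% of the (protein, process)
annotations in the analyzed set (a protein with several processes
qualifies if any passes; the denominator can be switched to proteins); and
betweenness centrality in the top decile of nonzero scores — the
centrality cutoff is a package choice, as no published threshold exists.
A missing evidence source skips its criterion with a warning instead of
silently reporting FALSE.

## SparCC co-occurrence network

Abundances are compositional after normalization, so Pearson correlations
on raw columns are biased; the package implements SparCC. The variation
matrix t*ᵢⱼ* = var log(xᵢ/xⱼ) is compositionally invariant. Under the
sparsity assumption the row sums of T give a linear system for the basis
log-variances ωᵢ²; the system solved by `sparcc_correlations()` is exactly
the least-squares normal-equation solution of the pairwise system
t*ᵢⱼ* ≈ ωᵢ² + ωⱼ², which is what the test-suite oracle solves directly by
QR. Correlations follow as ρ*ᵢⱼ* = (ωᵢ² + ωⱼ² − t*ᵢⱼ*)/(2ωᵢωⱼ), clipped
to [−1, 1]. The most-correlated pair above `exclusion_threshold`
(default 0.1) is iteratively removed from the variance estimation and the
system re-solved — strong pairs violate sparsity and would inflate their
members' variances — while the final ρ is reported for all pairs.
Numerical choices: abundances are continuous TAS values rather than
counts, so the Dirichlet resampling of count-based SparCC is omitted and
zeros are protected by a pseudocount (default 1 TAS unit, negligible
against typical 10⁵-scale values); components whose estimated basis
variance turns negative are flagged unreliable and their correlations set
to NA with a warning; a planted ρ = 0.8 pair in a 5-component system is
recovered within ±0.1 from 1000 runs.

`build_network()` keeps edges with |ρ| ≥ 0.6 by default (configurable; no
published threshold exists) and stores the signed correlation as the edge
weight. Betweenness centrality uses the distance transform 1 − |ρ| (strong
co-occurrence = short path), zero-length edges guarded at 10⁻⁶,
unnormalized scores by default. The Brandes implementation (igraph) is
cross-checked exactly against naive all-pairs shortest-path enumeration on
random graphs of up to 8 nodes.

## Physicochemical panel

The sequence calculators reproduce the ProtParam conventions: mole-percent
composition with ambiguous `X` excluded from denominators (and counted);
GRAVY as the mean Kyte–Doolittle hydropathy; theoretical pI by bisection
of the Henderson–Hasselbalch net charge on pH 0–14 to 10⁻⁴, using the
Bjellqvist pKa set including the residue-dependent terminal exceptions;
the Guruprasad instability index (10/L × Σ DIWV over ordered adjacent
dipeptides, threshold 40); the aliphatic index X(Ala) + 2.9 X(Val) +
3.9 (X(Ile) + X(Leu)); and atomic composition as the residue formula sum
minus (L − 1) waters. The DIWV and pKa tables are vendored as package
constants with provenance noted in the source. All calculators are tested
to 10⁻³ against an independent reference implementation on a frozen
20-sequence panel, and GRAVY's reversal invariance vs. the instability
index's order dependence are both asserted. The Fig-7-style
`ratio_screen()` flags residues whose between-group mole-percent ratio
falls in either tail (≤ 0.5 or ≥ 1.5, boundaries inclusive — the published
inequality is read as the union of the two tails); an infinite ratio from
a zero denominator is flagged. `group_property_summary()` subsamples large
groups (the study design caps the tick sialome-only group at 100 proteins)
under a fixed seed, since the original random selection is unknowable.

## Elemental composition and α-Gal

`summarize_elements()` classifies elements by mean atomic percent
(> 10% high, < 1% low) and runs a one-way ANOVA across T1–T3 with scans as
observations; elements detected in fewer than 2 samples are excluded as
rare, matching the treatment of Br and Zn. ANOVA degenerate cases are
explicit: all-identical observations give F = 0, p = 1; zero within-group
variance with differing means gives F = ∞, p = 0.
`correlate_composition()` computes the Spearman correlation (average
ranks) between a protein group's computed C/N/O/S percentages and the
T1–T3 mean measured percentages; rank-concordant vectors give exactly 1.

The ELISA model treats the calibration intercept as assay background
carried by every well, blanks included. `calibrate_plate()` therefore
blank-corrects the standards before the OLS fit, after which
`quantify_alpha_gal()` inverts the line on blank-corrected sample means
and scales by the coated amount (100 ng/well → ×10 to ng per µg protein).
This makes zero-noise quantitation the exact inverse of the generator,
which the acceptance suite asserts at 10⁻¹⁰. Negative blank-corrected
values are floored at zero and flagged rather than propagated. The α-Gal
molecular formula string printed in the source study is internally
inconsistent with the named trisaccharide; it is treated as metadata only
and never computed on.

## Problem sizes and reproducibility

The validation experiments use 200 proteins (recovery), 2000 proteins
(null calibration), 1000 runs (SparCC planted pair), 100 random graphs of
≤ 8 nodes (betweenness oracle) and 1000 replicates (type-I rates) — sizes
chosen so the whole suite exercises every code path with tight Monte-Carlo
error in well under a minute. Every stochastic component takes an explicit
seed; `run_pipeline()` echoes its configuration into the output directory
and regenerating with the same seed reproduces every output file
byte-identically.

## Known limitations

The profile template table is a reconstruction, not a published fact; real
analyses should review it against their own expectations (it is fully
configurable). The raw-α significance gate leaves ~12% of true
housekeeping proteins outside that category by construction. TAS
normalization inherits the constant-total assumption discussed above.
SparCC's sparsity assumption degrades when many strong correlations
coexist in a small panel; the exclusion loop mitigates but does not remove
this. The physicochemical panel covers the properties used in the
analysis, not the full ProtParam output (no extinction coefficients or
half-life).
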