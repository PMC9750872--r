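---
title: "Scoring chemical-genetic CRISPRi screens: model, parameters and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring chemical-genetic CRISPRi screens}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chemgenscreen)
```

## The measurement model

A pooled CRISPRi chemical-genetic screen infects a cell population with a
genome-scale sgRNA library, splits it into an untreated arm and a
drug-treated arm, and uses sequencing of the integrated sgRNA cassettes to
ask which knockdowns change drug sensitivity. Each sgRNA's abundance acts as
a barcode for the fitness of the cells carrying it. Two phenotypes are
defined per sgRNA *i*:

* growth: `gamma_i = (e_i(untreated, t0) − median_NT e) / D_u`
* drug sensitivity: `rho_i = (e_i(treated, untreated) − median_NT e) / ΔD`

where `e_i(A, B) = log2(f_i(A) / f_i(B))` is the log2 change in relative
frequency, `median_NT` is the median over all non-targeting control sgRNAs,
`D_u` is the total number of population doublings of the untreated arm, and
`ΔD` is the doubling difference between the untreated and treated arms.
Dividing by doublings puts phenotypes on a per-doubling scale, so screens of
different durations are comparable; subtracting the non-targeting median
removes the arm-wide shift that any depth or bottleneck artifact induces. A
negative `rho` means the knockdown depletes under drug — it *sensitizes*; a
positive `rho` protects.

Gene-level scores are built in three steps:

1. **Collapse**: the gene (per TSS) phenotype is the mean of its top three
   sgRNAs by absolute value — strong knockdown guides dominate, weak or
   inactive guides are ignored, and the sign is preserved.
2. **Test**: a two-sided Mann-Whitney U test compares *all* of the gene's
   sgRNA phenotypes with the non-targeting phenotypes (the test uses every
   guide, not just the top three).
3. **Calibrate and call**: negative-control *pseudo-genes* — random groups
   of non-targeting sgRNAs of the same size as a typical gene — are scored
   identically. Their collapsed phenotypes define `mu_NCG` and `sigma_NCG`;
   the gene z-score is `(phenotype − mu_NCG)/sigma_NCG`, and the hit
   statistic is the discriminant score `|z| · (−log10 p)`, thresholded at 7.
   Using `|z|` makes the boundary two-sided, so sensitizing and protective
   hits are both callable. For genes with several annotated transcription
   start sites, each TSS is scored independently and the TSS with the lowest
   Mann-Whitney p is kept verbatim.

## Parameters that matter

| parameter | default | meaning |
|---|---|---|
| `pseudocount` | 10 | added to every count before frequencies; keeps log-ratios finite at zero counts and shrinks noisy low-count ratios |
| `doublings_untreated` (`D_u`) | none — must be set | physical normalizer of gamma (doublings) |
| `doubling_difference` (`ΔD`) | 6.1 | physical normalizer of rho (doublings); 6.1 matches the screen design this package targets |
| `min_reads` | 0 (off) | optional t0 count floor; filtered sgRNAs become missing, never zero |
| collapse `k` | 3 | top-k by absolute value in the gene collapse |
| `threshold` | 7 | discriminant hit threshold |
| `n_pseudo`, `size` | #gene groups, modal sgRNAs/gene | pseudo-gene count and size; matching the real-gene count makes the z calibration comparable |
| `cadd_min` | 15 | CADD Phred retention floor for SNVs in the mutation analysis |
| `min_group` | 2 | smallest mutant/wild-type group for a testable gene |

The doubling normalizers are deliberately *not* defaulted from thin air: the
pipeline refuses to emit phenotypes without them, because they are physical
quantities of the experiment, not tuning knobs. The pseudocount and
`min_reads` are the two places where reasonable analyses can differ; both
are recorded in the output metadata, and `min_reads` is off by default so
the scoring follows the written procedure as closely as possible.

Design choices that were genuinely open, and how they were resolved:

* **z centering.** Only the standard deviation of the negative-control
  genes is prescribed by the hit rule; we also subtract their mean. After
  median normalization it is empirically near zero, but the top-k-by-|.|
  collapse gives pseudo-genes a slightly positive phenotype (an absolute
  value of noise), and subtracting the mean removes that bias from z.
* **Signed phenotype, absolute z.** The collapse keeps the sign (so the
  direction of a hit is meaningful), while the discriminant uses `|z|` so
  the threshold is symmetric.
* **Ties.** Ties in the top-k collapse are broken by sgRNA id; ties in the
  TSS collapse by larger absolute phenotype, then TSS label. Both are
  arbitrary but deterministic, so reruns are byte-identical.
* **Mann-Whitney implementation.** Exact enumeration when both groups have
  ≤ 8 tie-free observations, otherwise the tie-corrected normal
  approximation with continuity correction (`stats::wilcox.test` provides
  both regimes). The exact path is verified in the test suite against an
  independent exhaustive enumeration of all rank assignments for every
  configuration with group sizes up to 6. The approximation tracks the
  exact p to within 0.02 once both groups have ≥ 5 observations; at 3 vs 3
  the worst-case gap is 0.0375 — with 5 sgRNAs per gene and hundreds of
  non-targeting controls, real screens never sit in that corner.
* **Multiple testing.** The hit rule is the discriminant threshold, as in
  the screen design this package follows; a BH-FDR column is emitted for
  reference but never gates hit calls.

## What the simulator emulates — and what it does not

`simulate_library()` / `simulate_screen()` generate screens with known
ground truth. The model:

* t0 abundance skew: log-normal (`t0_sigma`, default 0.5), matching the
  uneven representation of real libraries;
* true effects: a configurable fraction of genes (default 5%) get a
  non-zero rho drawn from a two-sided distribution (default magnitudes
  0.3–0.6, 70% sensitizing), similarly for gamma; all other genes and all
  non-targeting controls are exactly null;
* guide heterogeneity: each sgRNA has an activity `a_i ∈ [0, 1]`
  (default uniform on [0.7, 1], a well-designed library) that scales its
  gene's effect;
* dynamics: expected log2 enrichment is `D_u · a_i · gamma_g` (untreated vs
  t0) and `ΔD · a_i · rho_g` (treated vs untreated) — exponential
  growth/selection summarized per doubling. Drug exposure enters only
  through `ΔD`, the same summary the scoring model uses; dosing schedules
  are not modeled.
* counts: multinomial at fixed depth, or Dirichlet-multinomial when
  `dispersion > 0`. The dispersion is parameterized as the approximate
  excess squared CV of a typical sgRNA's frequency (default 0.05, i.e.
  ~22% extra CV), emulating bottleneck and PCR noise.

Deliberately *not* modeled: infection multiplicity and selection kinetics,
cell-cycle structure, guide-specific off-target effects, positional biases
or base-quality structure in reads. Passing recovery tests on these
simulations therefore shows that the scoring mathematics is correct and
well calibrated under the stated noise model — it does not certify
performance against pathologies the simulator does not generate.

Default simulator choices that the design left open: the untreated arm's
total doublings default to `D_u = 10` (roughly three weeks of a fast-growing
adherent line); sequencing coverage defaults to 500 reads/sgRNA. Both are
ordinary values for this screen format and are free configuration.

## Numerical contracts and degenerate inputs

* The non-targeting median of gamma and rho is exactly zero after
  normalization (asserted per run; with an even number of controls the
  residual is at floating-point rounding level).
* All randomness flows from one integer seed through fixed per-stage
  offsets; identical config + seed reproduces outputs byte for byte, and
  simulation draws are keyed to sorted sgRNA ids, so the library's row
  order is irrelevant.
* Zero-variance controls (`sigma_NCG = 0`), missing doubling normalizers,
  empty groups in the Mann-Whitney test, and libraries without
  non-targeting records are hard errors, not silent defaults. Fully tied
  Mann-Whitney inputs return p = 1.
* Filtered sgRNAs are missing values, never zeros, so downstream collapses
  skip them instead of shrinking gene scores toward null.
* 4PL fits run bounded Levenberg-Marquardt from a grid of starts (hill ∈
  {0.5, 1, 2} × 5 log-spaced IC50 starts) and keep the lowest residual sum
  of squares; `bottom ∈ [0, 100]`, `top ∈ [50, 150]`, `hill ∈ (0, 10]`. An
  IC50 outside the tested range is reported but flagged extrapolated.

## Validation summary

The test suite and `scripts/acceptance.R` recompute, from scratch:

* exact Mann-Whitney p equals exhaustive enumeration on every tie-free
  configuration with group sizes ≤ 6 (including the complete-separation
  3 vs 3 case, p = 0.1);
* on 20 simulated screens (200 genes, 5 sgRNAs/gene, 400 non-targeting,
  500 reads/sgRNA), recovered rho for hit genes is within 0.05 of truth on
  average (fully active guides, multinomial counts), hit-calling
  sensitivity at discriminant ≥ 7 is ≥ 0.9 and the pseudo-gene hit rate is
  ≤ 1% under the default activity spread and overdispersion;
* per-gene Wilcoxon type-I error on a 2,000-gene null mutation cohort is
  0.05 ± 0.02 at α = 0.05;
* FASTQ emission followed by counting returns the input counts exactly at
  zero error rate, and seeded reruns are identical;
* noise-free 4PL curves are recovered to numerical precision; at 5%
  viability noise with 3 replicates the mean relative IC50 error over 100
  simulated plates stays under 20% (per-plate errors at this noise level
  have median ≈ 0.09 and can individually approach ~0.4 at the global
  optimum — the average is the meaningful summary).

Problem sizes in the benchmark scripts (2,000-gene simulated screen in
`analysis/`, 200-gene multi-seed benchmarks) were chosen so the full
analysis re-runs in minutes on a laptop; the scoring itself is linear in
the number of sgRNAs and handles genome-scale libraries.

## Known limitations

* Exact-match counting only (forward strand, fixed offset, optional
  substring scan); mismatch-tolerant alignment is out of scope, so heavily
  error-prone sequencing will undercount uniformly.
* Replicate arms are averaged after per-replicate normalization; no
  replicate-variance model is fitted.
* The mutation analysis consumes CADD Phred scores; it never computes
  deleteriousness itself, and its variant-class vocabulary, while
  extensible, must be mapped explicitly for unusual MAF dialects.
* IC50s from 4PL fits are point estimates; no confidence intervals are
  propagated into the association stage (ranks are insensitive to modest
  per-line error, which is the reason the association uses a rank test).
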