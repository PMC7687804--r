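---
title: "Methods: proteome dynamics from pulsed SILAM spectral counts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: proteome dynamics from pulsed SILAM spectral counts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(silamdyn)
```

## The measurement model

A pulsed SILAM experiment replaces dietary lysine with Lys(6) shortly before
the challenge, so proteins synthesized during the pulse carry +6.0201 Da per
labeled lysine while pre-existing proteins do not. After trypsin digestion
and database search, each peptide-spectrum match (PSM) arrives with its
peptide sequence, inline modifications, protein mapping and a spectral
count — the number of MS/MS spectra matched to the peptide, a
semi-quantitative abundance proxy. `silamdyn` works entirely on these
post-search tables; it does not touch raw spectra and assumes identification
error has been controlled upstream (e.g. 1% FDR).

Three independent signals are read from each PSM:

1. **Label status.** A peptide with at least one `label-K6` modification is
   newly-synthesized evidence; its mass shift is exactly
   `6.0201 × n_labeled_lysines` Da. Peptides without lysine can never be
   labeled and are (by default) retained in peptidome denominators, since
   the quantity of interest is the labeled share of *all* analyzed peptides.
2. **Terminal specificity.** Trypsin cleaves C-terminal to K/R except before
   P. A terminus that coincides with neither a cleavage site nor a protein
   terminus witnesses endogenous proteolysis. Both termini tryptic =
   fully tryptic; exactly one = semi-tryptic; neither = non-tryptic.
3. **Modifications with coordinates.** Phospho positions on the peptide are
   translated to protein coordinates through the peptide's mapped start.

## Estimators

**Labeled proteome fraction** (per condition × layer): proteins with labeled
evidence in ≥ 2 animals over proteins detected in ≥ 2 animals. The
two-animal consistency rule mirrors the upstream convention that identifications
seen in a single animal are unreliable; it is applied symmetrically to the
numerator and the denominator so that detection noise cancels rather than
biasing the ratio.

**Labeled peptidome fraction**: distinct labeled peptide sequences over all
distinct sequences in the group (a sequence counts as labeled if any PSM of
it carries the label); a spectral-count-weighted variant is also reported.

**Incorporation profiles**: per protein and group, `labeled_sc / total_sc`.
Spectral-count weighting is the default because the downstream ratios are
defined on summed spectral counts; the distinct-peptide-weighted fraction is
emitted alongside since either convention is defensible. Cumulative
frequency curves over proteins are the comparison view; a two-sample KS
distance is provided as plumbing, with no claim to reproduce any particular
published curve normalization.

**Regulation.** Per protein and layer, counts are summed per animal into
newly-synthesized (`nsp_sc`, labeled) and pre-existing (`nnsp_sc`,
unlabeled) pools. The LPS/Control ratio pools counts across animals before
dividing (no pseudocounts); a zero denominator is categorical — labeled
evidence only under LPS is an *exclusive synthesis* call, never an infinite
ratio. Significance uses Student's pooled-variance *t*-test on per-animal
sums (Welch optional); up/down calls require p ≤ 0.05 **and** fold ≥ 1.5
jointly. No multiple-testing correction is applied to the per-protein tests,
matching the raw-p convention of the source analyses; group-level count
comparisons use the same *t* machinery. Degenerate inputs are categorical:
fewer than 2 animals per side is not testable (`NA`), identical constant
groups give p = 1, constant but different groups give p at machine epsilon.

**Shared peptides** distort spectral-count ratios, so the default policy
counts only peptides mapping to a single protein; an all-mapped option
exists. Within a multi-protein claim, the mapping with the highest terminal
specificity provides the coordinates.

**Turnover** is the summed spectral count of peptides with at least one
non-tryptic terminus, per protein and group. Semi-tryptic peptides are
included by default: in a trypsin-digested sample endogenous proteolysis
typically leaves one tryptic and one endogenous terminus, so requiring both
termini non-tryptic would discard most genuine evidence; the strict variant
is available (`include = "non_only"`). Each non-tryptic N-terminus at
protein position *s* maps a cleavage after residue *s − 1*; a non-tryptic
C-terminus at *e* maps a cleavage after *e*. Raw counts are used with no
library-size normalization (an optional scaling exists but is off), since
the spectral-count convention reports unnormalized evidence.

One digestion subtlety: a peptide beginning at protein position 2 of a
Met-initiated protein is treated as having a tryptic N-terminus, because
initiator-methionine excision otherwise mislabels canonical N-terminal
peptides as turnover evidence.

**Phosphosites** are keyed by (accession, position, residue). Observations
below localization score 1000 are discarded; the threshold is read as
≥ 1000 because the search engine reports 1000 as maximal confidence and a
strict equality filter would be brittle against rescaled scores. The score
is the only automated surrogate for manual validation, and output metadata
says so. A site is *disease-specific* in a layer when observed in at least
one LPS sample and no Control sample of the same layer; cross-layer evidence
does not veto. The symmetric control-specific flag is mutually exclusive by
construction.

## The synthetic-data generator

`generate_psm_tables()` emulates the study design so that every estimator
can be validated against ground truth: a Met-initiated random protein
database at roughly mammalian residue frequencies (K + R ≈ 15%, so tryptic
peptides have usable lengths); a fixed per-protein panel of tryptic peptides
(detectability is a property of the peptide, so the panel is shared across
samples); negative-binomial spectral counts per peptide and animal, with
zeros dropping the observation; Bernoulli Lys(6) labeling of K-containing
peptides of pool proteins; semi-tryptic fragments injected by truncating a
tryptic peptide at a verified non-tryptic internal position; and candidate
phosphosites observed per animal with condition-specific probabilities.

Default parameters and why:

* **Design**: 2 conditions × 3 layers × 3 animals per condition — six mice
  split into two groups, each contributing every layer.
* **Pool probabilities**: Control 0.31/0.29/0.34 and LPS 0.16/0.18/0.16 for
  GC/EC/SMC, the reported per-layer labeled-proteome fractions (preset
  `fig1_fractions`; preset `null` equalizes the conditions).
* **Nested pools**: within a layer, both conditions share a latent
  per-protein synthesis propensity, so the LPS pool nests inside the Control
  pool. Endotoxemia suppresses synthesis rather than reshuffling it, and
  under the null this makes the two conditions exchangeable.
* **Spectral counts**: negative binomial with mean 3 and dispersion 0.5
  (variance = μ + 0.5 μ²). Overdispersed counts are the accepted model for
  spectral counting; the dispersion is a free parameter recorded in the
  truth JSON.
* **Coverage and within-pool labeling**: up to 30 panel peptides per
  protein and a 0.65 per-peptide labeling probability for pool proteins.
  These were fixed once by a prospective power analysis of the study design:
  with 3 animals per group and a pooled *t*-test on overdispersed counts, a
  well-covered protein needs on the order of ten labeled peptide species for
  a 4-fold suppression to be detectable, which corresponds to the deep
  HPLC-fractionated coverage the analysis targets. A 24–48 h pulse against
  protein half-lives of 1–2 days also makes a high labeled share *within*
  newly synthesized proteins plausible.
* **Effect model**: 20% of proteins have labeled-count means scaled by 0.25
  under LPS (the global NSP suppression), leaving unlabeled counts
  untouched.
* **Phospho model**: one candidate site on a covered S/T/Y residue for a
  configurable fraction of proteins; detection 0.05 (Control) vs 0.3 (LPS)
  per animal; localization score 1000 with probability 0.9, otherwise
  uniform below the filter.

Two reparameterizations deserve a note. The per-peptide labeling invariant —
only K-containing peptides can carry the label — means a requested
*marginal* peptidome labeling rate r (e.g. 5.1%) is realized by labeling
K-containing peptides with probability r / f_K, where f_K is the
K-containing share of the generated peptide universe; this is a
deterministic change of variables, not a calibration. Second, "truly
modulated" in power checks means modulated *and* labeled under both
conditions: a protein whose synthesis stops entirely has no finite ratio and
is correctly reported in the exclusive-synthesis category instead.

What the generator does **not** emulate: correlated peptide detectability
(ionization efficiency), protein-abundance heterogeneity across orders of
magnitude, shared peptides between homologous proteins, decoy/FDR
structure, chimeric spectra, and batch effects between runs. Passing the
recovery tests therefore shows the estimators are correct under the stated
noise model, not that real data meet that model.

## Numerical and design choices

* Modification deltas in PSM tables are matched to the vocabulary within
  ±0.01 Da, since search-engine exports print rounded deltas; the exact
  vocabulary mass replaces the printed one.
* Peptide occurrences in a protein are searched with overlap; when a peptide
  occurs at several positions the call maximizing specificity is kept and
  flagged multi-mapped. Fully > semi > non is the resolution order, ties go
  to the first position.
* Coordinates are 1-based inclusive throughout.
* All tables are UTF-8 TSV with `#` comments ignored and decimal points
  only; every writer round-trips through its reader. The run report
  contains versions, config echo, per-stage record counts and warnings, and
  deliberately no timestamps, so identical inputs give byte-identical
  output trees.
* Problem sizes in the validation suite (500 proteins × 3 animals × 10
  seeds for fraction recovery; 20 × 300 for the null; 10 × 300 for power)
  were chosen so each property is measured well inside its tolerance while
  the whole suite stays comfortably runnable on a laptop.

## Known limitations

* Spectral counting saturates for abundant proteins; ratios near 1.5 on
  low-count proteins are noisy, and the joint p-and-fold rule is the guard.
* The *t*-test on raw counts with n = 3 per group is the study's own
  convention, not an optimal count model; a negative-binomial GLM would be
  the modern choice but would not reproduce the published decision rule.
* Turnover evidence cannot distinguish endogenous proteolysis from in-vitro
  degradation during sample handling; the Control arm is the implicit
  baseline.
* Disease-specificity is a presence/absence call and inherits detection
  noise: a site near the detection limit in Control can be mislabeled
  LPS-only. The per-animal counts with their test quantify the aggregate
  trend instead.
* Isotope-envelope (MS1) incorporation estimation, kinetic half-life
  modeling from time courses, protease-specificity inference and pathway
  enrichment are out of scope.
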