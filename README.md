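# silamdyn

Proteome dynamics from pulsed stable-isotope labeling (SILAM) and spectral
counting, for vascular-bed proteomics of endotoxemia.

## The problem

In a pulsed SILAM experiment, dietary lysine is replaced by heavy Lys(6), so
every protein synthesized after the switch carries a +6.0201 Da mass tag per
lysine. Combined with layer-resolved decellularization of the vasculature
(glycocalyx GC, endothelial cells EC, smooth muscle cells SMC) and an LPS
endotoxemia challenge, this separates, per vascular layer and condition:

* the **newly synthesized proteome** (NSP — proteins with Lys(6)-labeled
  peptide evidence) from the pre-existing pool (N-NSP);
* **protein turnover**, read out from peptides whose termini do not match
  trypsin specificity and therefore witness endogenous proteolysis;
* **disease-specific phosphosites**, observed only under LPS in a layer.

`silamdyn` takes post-search PSM tables (peptides, inline modifications,
spectral counts), a protein FASTA and a sample design, and computes the full
downstream analysis. Quantities follow the field's spectral-count
conventions:

* per-protein incorporation fraction: `labeled_sc / total_sc`;
* condition ratios pooled over animals: `NSP_LPS/Control = Σ nsp_sc(LPS) / Σ
  nsp_sc(Control)`, with zero denominators reported categorically (N.D. /
  exclusive synthesis), never as infinities;
* regulation calls: Student's *t* on per-animal summed counts, called
  up/down at p ≤ 0.05 **and** fold ≥ 1.5 (or ≤ 1/1.5);
* turnover score: summed spectral counts of peptides with ≥ 1 non-tryptic
  terminus, with endogenous cleavage sites mapped to protein coordinates;
* phosphosites filtered at localization score (Ascore) ≥ 1000 and called
  disease-specific when absent from all same-layer Control samples.

A synthetic-data generator (`synthetic_config()`, `generate_psm_tables()`)
emulates the whole design — Bernoulli Lys(6) labeling, negative-binomial
spectral counts, semi-tryptic fragment injection, condition-specific
phosphosites — with ground truth, so every stage is testable without any
data download.

## Worked example

```r
library(silamdyn)

sim <- generate_psm_tables(synthetic_config(n_proteins = 200, seed = 7))
fit <- proteome_dynamics(sim$psms, sim$design, sim$proteome)
fit
#> Proteome dynamics analysis (silamdyn)
#>   PSMs: 90564 in 18 samples; proteins with profiles: 200
#>   GC Control: labeled proteome 31.5% (63/200)
#>   EC Control: labeled proteome 26.0% (52/200)
#>   SMC Control: labeled proteome 36.0% (72/200)
#>   GC LPS: labeled proteome 19.5% (39/200)
#>   EC LPS: labeled proteome 15.0% (30/200)
#>   SMC LPS: labeled proteome 19.0% (38/200)
#>   Regulated proteins (|fold| >= 1.5, p <= 0.05): 25; exclusive: 80
#>   Turnover: 55 proteins with non-tryptic evidence; phosphosites: 40 (68 disease-specific site calls)
```

The per-layer labeled-proteome fractions recover the generator's pool
probabilities (Control 31/29/34%, LPS 16/18/16% for GC/EC/SMC) up to
sampling noise at 200 proteins. Individual downregulated proteins carry the
NSP evidence:

```r
head(subset(fit$regulation, call == "down",
            c(accession, layer, nsp_ratio, p_value_nsp)), 3)
#>    accession layer nsp_ratio  p_value_nsp
#> 14    SYN014    EC 0.2162162 5.394983e-06
#> 18    SYN018    EC 0.2676056 2.484095e-03
#> 33    SYN033    EC 0.2485876 6.065243e-04
```

Here `nsp_ratio` ≈ 0.25 reflects the generator's 4-fold suppression of
labeled-peptide counts under LPS for modulated proteins. `summary(fit)`,
`plot(fit)` (cumulative incorporation curves) and
`plot(fit, type = "turnover")` give the standard views;
`write_pipeline_results(fit, "out/")` writes every table as TSV plus a JSON
run report. File-based runs use `run_config()` / `run_pipeline()`, and
`inst/scripts/silamdyn.R` wraps simulation and analysis for shell use.

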