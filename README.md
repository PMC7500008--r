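# lymphomiR

Identification of miRNA expression signatures associated with lymphatic
dissemination (pathological lymph-node status N0 vs N1) in bulk miRNA-Seq
count data, with an emphasis on testable, reproducible statistics.

The package is aimed at analysts working with miRNA-Seq of tumor cohorts
who want the complete chain — normalization, differential expression,
signature scoring, enrichment — as ordinary R functions with validated
inputs and seeded simulations, rather than as an ad-hoc script.

## What it computes

Given a miRNA x sample matrix of raw read counts and per-sample labels
(N0/N1, optional Gleason score):

1. **Normalization** — TMM, RLE (median-of-ratios), upper-quartile or
   total-count factors, and counts per million
   `CPM = count / library_size * 1e6 / factor`, plus concordance
   diagnostics between methods.
2. **Consensus differential expression** — each miRNA is tested with a
   negative-binomial quasi-likelihood F-test on counts *and* the
   Mann-Whitney test on CPM; Benjamini-Hochberg FDR is applied per test
   family, and a miRNA is called only when both FDRs are < 0.05 and
   |fold change| ≥ 1.5. Upregulated calls are "N1-miRs", downregulated
   are "N0-miRs". Per-miRNA portions of samples with high (> mean x 1.5)
   and low (< mean / 1.5) relative expression are compared between
   cohorts as a descriptive complement.
3. **Signature analysis** — per sample, the score
   `Δ = mean(centered log2 CPM over N1-miRs) − mean(over N0-miRs)`
   dichotomizes the cohort into G0 (Δ < 0) and G1 (Δ > 0); enrichment of
   G1 among N1 samples is tested with Fisher's exact test, and the
   Spearman correlation structure of the two modules (within- and
   cross-module averages) plus correlations with node status and Gleason
   score are reported.
4. **Synthetic data** — a seeded negative-binomial generator with
   log-normal library sizes, two anti-correlated planted modules driven
   by a group-linked latent factor, optional composition bias, and
   ground truth for sensitivity/FDR benchmarking.

See `vignettes/signature-methods.Rmd` for the full methods account.

## Worked example

```r
library(lymphomiR)

sim <- generate_dataset(synthetic_spec(seed = 42))   # 300 miRNAs, 24 N0 + 20 N1
report <- run_pipeline(pipeline_config(
  sim$dataset$counts, sim$dataset$annotations,
  n1_set = sim$truth$up_set, n0_set = sim$truth$down_set))
print(report)
```

```
lymphomiR run report (v0.1.0)
input: 300 miRNAs x 44 samples; 300 passed the expression filter
normalization: TMM
consensus calls: N1_miR=1, N0_miR=1, not_significant=298
signature sets: 9 N1-miRs, 9 N0-miRs
   N0 N1
G0 18  3
G1  6 17
Fisher exact p (G x N): 8.657e-05
avg Spearman r: within-N1 0.299, within-N0 0.438, cross -0.380
```

Reading the output: all 300 simulated miRNAs pass the CPM filter; at
this noise level the conservative two-test consensus calls only two of
the eighteen planted miRNAs, but the signature score built on the true
modules separates the cohort cleanly — 17 of 20 N1 samples land in G1
and 18 of 24 N0 samples in G0, with a Fisher p of 8.7e-05 — and the
modules show the expected correlation structure (positive within each
module, negative across). The DE table, signature scores, contingency
table and correlation matrix are all returned in the report object and,
when `outdir` is set, written as TSV.

A shell front end with `run`, `simulate` and `compare-norm` subcommands
is installed at `inst/scripts/lymphomir.R`.

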