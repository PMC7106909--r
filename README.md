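# tvburden

Tumor mutational burden (TMB) is widely used as a biomarker of response to
immune checkpoint inhibitors (αPD1, αCTLA4), yet its value depends heavily
on how it is measured: which variant callers are used, how their calls are
combined, how the burden is normalized for sequencing coverage, and where
the "high TMB" threshold is drawn. `tvburden` is an R package for
oncology/immunogenomics analysts that implements a standardized,
fully-tested version of this measurement stack and the statistics needed to
evaluate it — and to quantify its instability.

## What it computes

**Consensus, coverage-adjusted TMB.** Per-caller somatic call sets (VCF) are
normalized to left-aligned minimal representation and combined by an
ensemble rule (a variant must be reported by ≥ 2 callers, per variant
class). The consensus count is divided by the Mbp of genome covered at
depth ≥ 6:

TMB = |consensus variants| / Mbp covered (mutations/Mbp)

Cross-caller instability per patient is median(|TMB_i − TMB_j|) over caller
pairs divided by the median per-caller TMB; the cohort statistic is the
median over patients.

**Neoepitope burdens.** All 8–24 aa peptide windows covering a
protein-level variant are enumerated (an interior substitution yields
Σ_{L=8}^{24} L = 272 windows). A peptide counts toward the burden when it
binds ≥ 1 patient HLA allele at ≤ 500 nM. Weighted burdens multiply, per
epitope: allele count (A), amino-acid mismatches to the closest normal
peptide in the proteome by exhaustive BLOSUM62 scan (M), TCGA-expressed
transcripts of origin (T, 75th-quantile TPM > 1), and patient-expressed
transcripts (E, ≥ 1 read on any exon), i.e. burdens NB, NB·A, NB·M, NB·T,
NB·E and the products A·M, A·T, …, A·M·E.

**RNA-derived variant burdens.** Tumor-specific splice junctions: canonical
motif, absent from a normal-tissue junction compendium (one read in one
normal sample is disqualifying), not fully annotated, at least one end
annotated. Retained introns: kma-style transcript expression filters, then
an outlier rule keeping introns whose read count exceeds the transcript's
median intron count by > 3 (unscaled) MADs and is ≥ the transcript's own
count, minus retained introns seen in normal melanocytes. The **tumor
variant burden** is the exact sum

TVB = somatic variants + tumor-specific junctions + retained introns.

**Outcome evaluation.** ROC/AUC for every metric; logistic models of
response on log2 burden (therapy covariate where two arms exist) with
response probabilities at the cohort's 25th/75th burden percentiles and BH
correction; survival stratified by strict exceedance of the disease-matched
80th percentile with Cox PH and Kaplan–Meier fits; hazard-ratio sweeps over
thresholds; and the fraction of patients classified discordantly by two
metrics.

**Synthetic cohorts.** `generate_cohort()` produces a complete,
deterministic cohort bundle (per-caller VCF-compatible call sets, coverage
tracks, HLA genotypes, binding affinities, junction and intron tables,
clinical outcomes) with recorded ground truth, emulating a 431-patient
melanoma/NSCLC/prostate/RCC/MMR-deficient meta-cohort by default.

## Worked example

```r
library(tvburden)

cfg <- cohort_config(
  n_patients_per_type = c(melanoma = 60L, RCC = 20L),
  tmb_lognormal = list(melanoma = c(log(2700), 0.9), RCC = c(log(900), 0.7)),
  jx_lognormal = list(melanoma = c(log(120), 0.5), RCC = c(log(80), 0.5)),
  ri_lognormal = c(meanlog = log(15), sdlog = 0.5),
  compendium_size = 500L, n_transcripts = 300L,
  epitope_sample_rate = 0.02, seed = 2026L)

cohort <- generate_cohort(cfg)
#> Synthetic tumor cohort: 80 patients (60 melanoma, 20 RCC); 26 with RNA-seq

res <- run_pipeline(cohort)
res$report
#> Tumor variant burden evaluation report
#>   cohort caller variability (median): 0.227
#>   AUC entries: 52; response models: 8; survival cohorts: melanoma, RCC

bt <- res$burden_table
median(bt$tmb_adjusted)          # 12.22 mutations/Mbp in this simulation
median(bt$tvb - bt$tmb_raw, na.rm = TRUE)  # +119 variants from RNA sources

res$report$survival$melanoma
#> Survival fit (n = 60, 43 events): HR(high vs low) = 0.432 [0.169, 1.105], p = 0.07978
```

The report says: the default six simulated callers disagree by a median 23%
of each patient's TMB; among melanoma patients with RNA-seq, RNA variants
add a median 119 variants on top of the DNA count; and TMB-high melanoma
patients (above the within-disease 80th percentile) show a hazard ratio of
0.43 for death versus TMB-low patients in this simulated cohort — the
direction the generator planted (`hr_high_tmb = 0.6`), estimated with the
uncertainty a 60-patient cohort carries.

Smaller pieces work standalone:

```r
caller_variability(c(MuSE = 2100, MuTect = 2900, VarScan2 = 2500))
#> 0.16
attr(enumerate_snv_peptides(strrep("A", 101), 51), "n_windows")
#> 272
```

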