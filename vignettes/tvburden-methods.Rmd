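---
title: "Tumor variant burden metrics: models, filters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tumor variant burden metrics: models, filters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tvburden)
library(data.table)
```

# Overview

`tvburden` quantifies how much somatic variation a tumor carries, how much of
it could plausibly be seen by the immune system, and how well those
quantities predict immune checkpoint inhibitor (ICI) response and overall
survival. The pipeline has four layers:

1. **Consensus TMB** — multi-caller somatic variant consensus, coverage
   adjustment to mutations/Mbp, and cross-caller instability statistics.
2. **Neoepitope burdens** — enumeration of 8–24 aa peptide windows around
   protein-level variants, high-affinity MHC binder calling, and a family of
   weighted burdens.
3. **RNA-derived variants** — tumor-specific splice junctions (subtraction
   of a normal-tissue compendium plus annotation rules) and retained introns
   (expression filters plus a MAD outlier rule), combined with the DNA
   variant count into the tumor variant burden (TVB).
4. **Outcome evaluation** — ROC/AUC, logistic response models with quartile
   response probabilities, BH correction, 80th-percentile survival
   stratification with Cox/Kaplan–Meier fits, threshold sweeps, and
   classification-concordance diagnostics.

A deterministic synthetic-cohort generator supplies every input the pipeline
consumes, so all of this is testable without protected patient data.

# Consensus TMB

Each caller's call set is normalized to left-aligned minimal representation
before any set operation; variant identity is the `(chrom, pos, ref, alt)`
key, ignoring caller-specific fields. A variant enters the consensus set
when at least `min_callers` callers report it (default 2 — an ensemble rule;
exposed as a parameter). Because indel-capable callers differ from SNV
callers, consensus is computed per variant class over the callers declared
to emit that class.

Coverage-adjusted TMB divides the consensus count by the Mbp of genome
covered at depth ≥ 6 reads — twice the minimum depth the least sensitive
callers require for detection. Patients with multiple tumor samples
contribute the median across samples (midpoint convention for even counts).

The instability statistic for one patient is the median of absolute pairwise
TMB differences between callers divided by the median TMB across callers;
the cohort value is the median over patients. Absolute differences are the
only reading that keeps the statistic non-negative; the statistic is
invariant to caller labeling and to rescaling all TMB values, and it is
exactly zero when all callers agree. It operates on raw counts by default
(coverage-adjusted values are also accepted).

# Neoepitope enumeration and weighting

A substitution at interior position $p$ of a long protein is covered by $L$
windows of each length $L$, so lengths 8–24 give $\sum_{L=8}^{24} L = 272$
candidate peptides; truncation at a protein terminus only reduces this.
Frameshift (and retained-intron) tails are enumerated as every window
containing at least one novel residue, drawing up to $L-1$ flanking residues
from the unaltered upstream context; windows never extend past the tail
terminus, so a tail of $m$ novel residues yields exactly $m$ windows per
length (given sufficient context). Both enumerators are verified against a
brute-force oracle that scans all substrings. Distinct peptide strings are
the counting unit (window multiplicity is recorded but burdens count each
peptide sequence once per patient).

The closest normal peptide for mismatch weighting is found by an exhaustive
same-length ungapped BLOSUM62 scan over the reference proteome. A
database-search E-value ranking would agree in rank for ungapped same-length
matches, but depends on search heuristics and database size; the exhaustive
scan is deterministic and exact at the proteome sizes used here. Ties are
broken by weighted BLOSUM62 similarity — the match score normalized by the
candidate's self-score — then lexicographically. The mismatch count M is the
Hamming distance to the winner.

Burden weights per epitope:

* **A** — number of patient HLA alleles predicted to bind at ≤ 500 nM
  (inclusive threshold, as stated for high-affinity binding);
* **M** — amino-acid mismatches to the closest normal peptide;
* **T** — transcripts of origin whose disease-matched TCGA 75th-quantile TPM
  is strictly greater than 1 (strict, as stated);
* **E** — transcripts of origin with at least one RNA-seq read on any exon
  (patients with tumor RNA only; requesting E without RNA is an error).

A weighted burden is the sum over epitopes of the product of the requested
components; the raw burden is the count of epitopes with A ≥ 1. The
A-weighted burden therefore always dominates the raw burden, with equality
exactly when every binder is presented by a single allele.

# RNA-derived variants

**Junctions.** Coordinates follow the STAR `SJ.out.tab` dialect — 1-based
first and last intronic base — and all readers convert explicitly, because a
silent off-by-one is the dominant failure mode when mixing junction
dialects. A junction is putatively tumor-specific when it (1) has a
canonical splice motif (GT-AG, GC-AG, AT-AC), (2) appears in no normal
sample (a single supporting read in a single normal sample removes it; the
compendium is the union of all normal junction keys), (3) is not fully
annotated, and (4) has at least one annotated end. No minimum read support
is imposed on tumor junctions. Strand enters the identity key only when
both records have known strand; an unknown strand matches either
orientation (a logged choice; junction dialects disagree on strand
reporting).

**Retained introns.** Transcript-level filters: TPM ≥ 1 in ≥ 25% of
samples, ≥ 5 unique counts in ≥ 25% of samples, and mean intron retention
strictly between 0 and 100%. Within a passing transcript, an intron is
called retained when its read count exceeds the median intron count by more
than 3 median absolute deviations **and** is at least the transcript's own
read count (same sample). The MAD is unscaled — no 1.4826 normal-consistency
factor — because the rule is stated in MAD units, not robust standard
deviations; a `scaled` flag enables the factor for sensitivity analysis.
The comparison is strict for the MAD criterion and inclusive for the
transcript-count criterion, exactly as stated. Filters run per sample; a
patient's RI set is the union across their samples (the pooling convention
is not dictated by the rule itself). RIs found in normal melanocyte samples
are removed by exact set difference. RI peptides are translated across the
exon–intron boundary in the upstream reading frame until the first stop,
then enumerated like frameshift tails.

**TVB** is the exact sum of consensus somatic variants, tumor-specific
junctions, and tumor-specific retained introns, defined for patients with
tumor RNA.

# Outcome evaluation

* **ROC/AUC** via threshold sweep (the AUC equals the Mann–Whitney pair
  statistic; the package's tests enforce agreement to 1e-12 against a
  brute-force pair enumeration).
* **Logistic response models** on log2(burden + 1); the pseudocount of 1
  admits zero burdens and is configurable. Where a cohort has two
  single-agent therapy arms (aPD1 vs aCTLA4 in melanoma), the model includes
  a therapy indicator, and quartile response probabilities are reported per
  arm and marginalized over the observed therapy mix (the marginalization
  convention is a documented package choice). Combination-therapy patients
  and patients without documented response are excluded from response
  models; the latter remain in survival analyses. The slope is also reported
  as the percentage change in the odds of response per log2 fold change,
  $(e^{\beta}-1)\times 100$. Possible separation is flagged rather than
  silently diverging.
* **BH correction** within each cohort's set of response models.
* **Survival**: patients are "high" when their burden strictly exceeds the
  disease-matched 80th percentile (type-7 quantiles — linear interpolation
  between order statistics — declared because percentile thresholds are
  sensitive to the convention; with all burdens equal, nobody exceeds the
  quantile). Cox proportional hazards with Efron tie handling (a standard
  default), Kaplan–Meier curves with at-risk tables, optional administrative
  censoring at a stated horizon (e.g. 2885 days for the melanoma
  comparison), and a hazard-ratio sweep across percentile thresholds.
  Strata with zero events yield a flagged, non-estimable HR instead of an
  error; sweeps continue past flagged points.
* **Classification concordance**: the fraction of patients labeled
  high/low discordantly by two metrics at each percentile of a grid; for
  independent metrics at the 80th percentile the expected discordance is
  $2 \times 0.2 \times 0.8 = 0.32$.

# The synthetic cohort generator

The generator emulates a 431-patient ICI meta-cohort: 302 melanoma, 34
NSCLC, 10 prostate, 57 RCC and 28 mismatch-repair-deficient patients, with
per-type lognormal raw variant-count distributions anchored at the reported
per-type medians where available (635.5 prostate, 5632.5 MMR-deficient),
tumor RNA-seq restricted to melanoma and RCC (~25–27% of those patients),
per-type tumor-specific junction burden medians (2048.5 melanoma, 1301
RCC), retained introns in ~30% of RNA melanoma patients with median burden
929, ~85% SNVs among true variants, a melanoma therapy mix of roughly 20%
aPD1 / 77% aCTLA4 / 3% combination, and administrative censoring at 2885
days. Quantities with no reported value — lognormal spreads, caller
sensitivities (0.80–0.95) and false-positive rates (0.5–1.5 per Mbp),
coverage (150 ± 30 Mbp), the affinity model, response-model intercepts, the
baseline hazard (median survival ≈ 600 days) — are one-time choices pitched
at what is typical for WES-based ICI cohorts, and all are exposed in
`cohort_config()`.

Design points:

* **Seeding.** A single root seed derives a per-patient sub-seed from the
  patient id via a small string hash, so bundles are bit-reproducible and a
  patient's data do not depend on how many other patients are generated.
  Survival times use a second per-patient sub-seed because hazard classes
  are only known after the whole disease cohort exists (the 80th percentile
  is cohort-level).
* **Truth before noise.** True variant sets, true junction keys, true RI
  keys, response probabilities and hazard classes are recorded before caller
  noise, decoy junctions, or count noise are applied.
* **Caller noise.** Each caller's call set is a sensitivity-thinned subsample
  of the true variants of the classes it emits, plus Poisson false positives
  at its rate × coverage. With sensitivity 1 and rate 0, every caller
  reproduces the truth and the cohort instability statistic is exactly 0.
* **Junction universe.** Donor positions are partitioned by residue modulo 4
  into compendium / plantable tumor-specific / fully-annotated decoy /
  unannotated decoy classes, which guarantees planted junctions are disjoint
  from the normal compendium and makes planted-truth recovery exact.
* **Response and survival.** Response is Bernoulli with
  $p = \mathrm{logit}^{-1}(\beta_0 + \beta \log_2(\text{count}+1) +
  \delta\,[\text{aCTLA4}])$; survival is exponential with the hazard
  multiplied by a configurable factor for patients above their disease's
  80th percentile, with uniform plus administrative censoring.
* **Thinning.** Peptide-level simulation is thinned (each variant
  contributes peptides with probability `epitope_sample_rate`, 2 peptides
  per sampled variant), keeping binding tables desk-scale while preserving
  proportionality between peptide burdens and variant counts. Mismatch
  counts in the cohort bundle are planted draws; recomputing M from a
  proteome is exercised separately through `generate_proteome_and_variants()`
  and `closest_normal_peptide()`.
* **Variants are simulated at the genomic-coordinate level** (positions on a
  coverage-sized genome with REF/ALT alleles) so VCF round-tripping and
  normalization are exercised, but no read-level or signature-level realism
  is attempted.

What the generator does **not** emulate: mutational signatures, linkage
between variants and the peptides they produce (no codon-level translation
of somatic variants), germline phasing (so multi-variant phased peptides are
out of scope), caller error correlation, cohort batch effects, and
non-exponential survival shapes. Passing tests therefore demonstrate that
the pipeline's logic and statistics behave correctly under the assumed
structure, not that the assumed structure captures every property of real
tumors.

# Problem sizes and numerical choices

The test suite uses cohorts of ~12–18 patients for structural checks and
single-type cohorts of 300–400 patients × 100 replicates for parameter
recovery (logistic slope CI coverage, null rejection rate, Cox hazard-ratio
recovery) — sizes at which Wald intervals are well calibrated and the whole
suite stays fast. Burden medians in those recovery cohorts are set to ~60
variants; slope recovery depends on the spread of log2 burden (sdlog = 1),
not its location.

Degenerate inputs are handled explicitly: zero Mbp covered is an error
(TMB undefined, not infinite); a zero median across callers makes the
instability ratio an error; empty junction or RI sets yield zero burdens;
all-equal burdens classify nobody as high; zero events in a survival
stratum flag the fit. Ambiguous nucleotides stop RI translation at the
first ambiguous codon with a warning.

# Known limitations

* Single-variant peptide windows only; phased multi-variant neoepitopes are
  not constructed.
* The closest-normal scan is exhaustive and exact but O(proteome ×
  peptide length); it is intended for desk-scale proteomes, not the full
  human proteome in one pass.
* Processed-epitope burdens (proteasome/TAP modeling) are accepted as
  precomputed inputs, never recomputed.
* Real-data headline values (per-cohort AUCs, survival curves) depend on
  protected WES/RNA cohorts and are out of the package's reach; the
  package's claims are the combinatorial, filtering and statistical
  behaviors tested here.
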