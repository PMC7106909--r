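## Cohort configuration: the generator's defaults encode the study conditions
## of the meta-cohort the package emulates (cohort composition, per-type
## burden medians, RNA subset structure, therapy mix); distributional forms
## the source material does not state are fixed one-time choices documented
## in the methods vignette.

.default_caller_models <- function() {
  data.table::data.table(
    caller = c("MuSE", "MuTect", "Pindel", "RADIA", "SomaticSniper", "VarScan2"),
    sensitivity = c(0.92, 0.95, 0.80, 0.85, 0.88, 0.90),
    fp_rate = c(0.5, 1.0, 0.8, 1.2, 1.5, 1.0),   # false positives per Mbp
    classes = c("SNV", "SNV,insertion,deletion", "insertion,deletion",
                "SNV", "SNV", "SNV,insertion,deletion")
  )
}

#' Configuration for the synthetic cohort generator
#'
#' Defaults emulate a 431-patient immunotherapy meta-cohort: 302 melanoma,
#' 34 NSCLC, 10 prostate, 57 RCC and 28 mismatch-repair-deficient patients;
#' per-type lognormal raw variant-count distributions (medians 635.5 for
#' prostate and 5632.5 for MMR-deficient at the extremes); an RNA-seq subset
#' restricted to melanoma and RCC (~25% of those patients); per-type
#' tumor-specific junction burden medians (2048.5 melanoma, 1301 RCC);
#' retained introns in ~30% of RNA melanoma patients with median burden 929;
#' and a melanoma therapy mix dominated by aCTLA4 (about 195 aCTLA4 vs 50
#' aPD1 among response-evaluable patients).
#'
#' @param n_patients_per_type named integer vector, cancer type -> patients.
#' @param tmb_lognormal named list, type -> c(meanlog, sdlog) of the raw
#'   variant-count distribution.
#' @param caller_models data.frame with columns caller, sensitivity,
#'   fp_rate (false positives per Mbp), classes (comma-separated variant
#'   classes the caller emits).
#' @param coverage_mbp c(mean, sd) of covered genome size in Mbp.
#' @param snv_fraction fraction of true variants that are SNVs (the rest are
#'   split between insertions and deletions).
#' @param n_hla_alleles c(classI, classII): allele draws per patient per class.
#' @param affinity_model c(meanlog, sdlog, binder_fraction): non-binder
#'   affinities are 500 nM plus a lognormal(meanlog, sdlog) excess; a fraction
#'   binder_fraction of peptide-allele pairs is forced to <= 500 nM.
#' @param response_model c(beta0, beta_log2, offset_aCTLA4): logistic model
#'   of response probability on log2(true variant count + 1), with an additive
#'   offset for aCTLA4-treated patients.
#' @param survival_model c(baseline_hazard, hr_high_tmb): exponential event
#'   times with the hazard multiplied by hr_high_tmb for patients whose true
#'   variant count strictly exceeds their disease's 80th percentile.
#' @param censor_horizon administrative censoring horizon in days.
#' @param therapy_mix named list, type -> named probability vector over
#'   therapy arms.
#' @param response_missing_rate probability a patient lacks documented
#'   response status.
#' @param multi_sample_fraction fraction of patients with two tumor samples.
#' @param rna_fraction fraction of patients (in `rna_types`) with RNA-seq.
#' @param rna_types cancer types for which tumor RNA-seq exists.
#' @param ri_fraction fraction of RNA patients (in `ri_types`) with any
#'   retained introns.
#' @param ri_types cancer types eligible for retained introns.
#' @param jx_lognormal named list, type -> c(meanlog, sdlog) of the planted
#'   tumor-specific junction burden.
#' @param ri_lognormal c(meanlog, sdlog) of the planted retained-intron
#'   burden among RI-positive patients.
#' @param compendium_size number of junctions in the normal compendium.
#' @param n_transcripts size of the transcript pool.
#' @param introns_per_transcript c(min, max) introns per transcript.
#' @param epitope_sample_rate per-variant probability of contributing
#'   peptides to the binding table (thinning keeps peptide-level simulation
#'   desk-scale; burdens stay proportional to variant counts).
#' @param epitopes_per_variant peptides enumerated per sampled variant.
#' @param seed root integer seed; fixes all randomness end-to-end.
#' @return a validated list of class `cohort_config`.
#' @export
cohort_config <- function(
    n_patients_per_type = c(melanoma = 302L, NSCLC = 34L, prostate = 10L,
                            RCC = 57L, MMRd = 28L),
    tmb_lognormal = list(melanoma = c(log(2700), 0.9),
                         NSCLC = c(log(2250), 0.7),
                         prostate = c(log(635.5), 0.7),
                         RCC = c(log(900), 0.7),
                         MMRd = c(log(5632.5), 0.8)),
    caller_models = .default_caller_models(),
    coverage_mbp = c(mean = 150, sd = 30),
    snv_fraction = 0.8507,
    n_hla_alleles = c(classI = 6L, classII = 6L),
    affinity_model = c(meanlog = log(5000), sdlog = 1.2, binder_fraction = 0.009),
    response_model = c(beta0 = -3.8, beta_log2 = 0.3, offset_aCTLA4 = -0.65),
    survival_model = c(baseline_hazard = log(2) / 600, hr_high_tmb = 0.6),
    censor_horizon = 2885,
    therapy_mix = list(melanoma = c(aPD1 = 0.20, aCTLA4 = 0.77, combination = 0.03),
                       NSCLC = c(aPD1 = 1), prostate = c(aCTLA4 = 1),
                       RCC = c(aPD1 = 1), MMRd = c(aPD1 = 1)),
    response_missing_rate = 0.012,
    multi_sample_fraction = 0.06,
    rna_fraction = 0.27,
    rna_types = c("melanoma", "RCC"),
    ri_fraction = 0.30,
    ri_types = "melanoma",
    jx_lognormal = list(melanoma = c(log(2048.5), 0.5),
                        RCC = c(log(1301), 0.5)),
    ri_lognormal = c(meanlog = log(929), sdlog = 0.6),
    compendium_size = 5000L,
    n_transcripts = 2000L,
    introns_per_transcript = c(min = 4L, max = 10L),
    epitope_sample_rate = 0.05,
    epitopes_per_variant = 2L,
    seed = 1L) {
  cfg <- list(
    n_patients_per_type = n_patients_per_type, tmb_lognormal = tmb_lognormal,
    caller_models = data.table::as.data.table(caller_models),
    coverage_mbp = coverage_mbp, snv_fraction = snv_fraction,
    n_hla_alleles = n_hla_alleles, affinity_model = affinity_model,
    response_model = response_model, survival_model = survival_model,
    censor_horizon = censor_horizon, therapy_mix = therapy_mix,
    response_missing_rate = response_missing_rate,
    multi_sample_fraction = multi_sample_fraction,
    rna_fraction = rna_fraction, rna_types = rna_types,
    ri_fraction = ri_fraction, ri_types = ri_types,
    jx_lognormal = jx_lognormal, ri_lognormal = ri_lognormal,
    compendium_size = compendium_size, n_transcripts = n_transcripts,
    introns_per_transcript = introns_per_transcript,
    epitope_sample_rate = epitope_sample_rate,
    epitopes_per_variant = epitopes_per_variant, seed = seed
  )
  validate_cohort_config(cfg)
}

#' Validate a cohort configuration
#'
#' @param cfg a list of generator settings (see [cohort_config()]).
#' @return the validated config with class `cohort_config`.
#' @export
validate_cohort_config <- function(cfg) {
  fail <- function(field, why) {
    stop(sprintf("invalid configuration field `%s`: %s", field, why), call. = FALSE)
  }
  types <- names(cfg$n_patients_per_type)
  if (is.null(types) || any(!nzchar(types)))
    fail("n_patients_per_type", "must be a named vector of cancer types")
  if (any(cfg$n_patients_per_type < 0) || any(cfg$n_patients_per_type != floor(cfg$n_patients_per_type)))
    fail("n_patients_per_type", "counts must be non-negative integers")
  for (ty in types) {
    ln <- cfg$tmb_lognormal[[ty]]
    if (is.null(ln) || length(ln) != 2L) fail("tmb_lognormal", paste0("missing (meanlog, sdlog) for type ", ty))
    if (ln[2] <= 0) fail("tmb_lognormal", paste0("sdlog must be > 0 for type ", ty))
  }
  cm <- cfg$caller_models
  if (nrow(cm) < 1L) fail("caller_models", "need at least one caller")
  if (any(cm$sensitivity < 0 | cm$sensitivity > 1))
    fail("caller_models", "sensitivity must lie in [0, 1]")
  if (any(cm$fp_rate < 0)) fail("caller_models", "fp_rate must be >= 0")
  if (cfg$coverage_mbp[["sd"]] <= 0) fail("coverage_mbp", "sd must be > 0")
  if (cfg$coverage_mbp[["mean"]] <= 0) fail("coverage_mbp", "mean must be > 0")
  if (cfg$snv_fraction < 0 || cfg$snv_fraction > 1)
    fail("snv_fraction", "must lie in [0, 1]")
  af <- cfg$affinity_model
  if (af[["sdlog"]] <= 0) fail("affinity_model", "sdlog must be > 0")
  if (af[["binder_fraction"]] < 0 || af[["binder_fraction"]] > 1)
    fail("affinity_model", "binder_fraction must lie in [0, 1]")
  if (cfg$survival_model[["baseline_hazard"]] <= 0)
    fail("survival_model", "baseline_hazard must be > 0")
  if (cfg$survival_model[["hr_high_tmb"]] <= 0)
    fail("survival_model", "hr_high_tmb must be > 0")
  for (p in c("response_missing_rate", "multi_sample_fraction", "rna_fraction",
              "ri_fraction", "epitope_sample_rate")) {
    if (cfg[[p]] < 0 || cfg[[p]] > 1) fail(p, "must lie in [0, 1]")
  }
  for (ty in names(cfg$therapy_mix)) {
    mx <- cfg$therapy_mix[[ty]]
    if (any(mx < 0) || abs(sum(mx) - 1) > 1e-8)
      fail("therapy_mix", paste0("probabilities for type ", ty, " must be >= 0 and sum to 1"))
  }
  if (!.is_count(cfg$seed)) fail("seed", "must be a non-negative integer")
  if (!.is_count(cfg$compendium_size)) fail("compendium_size", "must be a non-negative integer")
  if (!.is_count(cfg$n_transcripts) || cfg$n_transcripts < 1)
    fail("n_transcripts", "must be a positive integer")
  structure(cfg, class = "cohort_config")
}

#' Default analysis thresholds of the pipeline
#'
#' All thresholds of the analysis, with their defaults: minimum read depth 6
#' for a base to count as covered; 2 callers for variant consensus; 500 nM
#' inclusive binding-affinity threshold; TCGA expression strictly above 1 TPM;
#' 3 MADs for the retained-intron outlier rule; 25% sample fraction for the
#' transcript filters; 80th percentile for high/low classification.
#'
#' @return a named list of thresholds.
#' @export
pipeline_params <- function() {
  list(min_depth = 6L, min_callers = 2L, affinity_threshold_nm = 500,
       tcga_tpm_min = 1, mad_multiplier = 3, tpm_min = 1, count_min = 5,
       sample_frac = 0.25, percentile = 80, pseudocount = 1)
}

#' Write a configuration to a YAML file
#'
#' @param cfg a `cohort_config`.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_config <- function(cfg, path) {
  ser <- unclass(cfg)
  ser$caller_models <- as.data.frame(ser$caller_models)
  ## named vectors become YAML maps (plain vectors would drop their names)
  for (nm in c("n_patients_per_type", "coverage_mbp", "n_hla_alleles",
               "affinity_model", "response_model", "survival_model",
               "ri_lognormal", "introns_per_transcript")) {
    ser[[nm]] <- as.list(ser[[nm]])
  }
  ser$therapy_mix <- lapply(ser$therapy_mix, as.list)
  yaml::write_yaml(ser, path)
  invisible(path)
}

#' Read a configuration from a YAML file
#'
#' @param path path to a YAML file written by [write_config()].
#' @return a validated `cohort_config`.
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  raw$caller_models <- data.table::as.data.table(
    lapply(as.data.frame(raw$caller_models), unlist))
  for (nm in c("n_patients_per_type", "coverage_mbp", "n_hla_alleles",
               "affinity_model", "response_model", "survival_model",
               "ri_lognormal", "introns_per_transcript")) {
    raw[[nm]] <- unlist(raw[[nm]])
  }
  raw$tmb_lognormal <- lapply(raw$tmb_lognormal, unlist)
  raw$jx_lognormal <- lapply(raw$jx_lognormal, unlist)
  raw$therapy_mix <- lapply(raw$therapy_mix, unlist)
  validate_cohort_config(raw)
}
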