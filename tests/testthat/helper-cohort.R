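# Small cohort configurations used across test files. Problem sizes are kept
# desk-scale; the statistical structure matches the generator defaults.

tiny_cohort_config <- function(seed = 7L, n_mel = 12L, n_rcc = 6L,
                               rna_fraction = 0.6, epitope_sample_rate = 0.3,
                               ...) {
  cohort_config(
    n_patients_per_type = c(melanoma = n_mel, RCC = n_rcc),
    tmb_lognormal = list(melanoma = c(log(60), 0.7), RCC = c(log(30), 0.6)),
    jx_lognormal = list(melanoma = c(log(25), 0.4), RCC = c(log(15), 0.4)),
    ri_lognormal = c(meanlog = log(8), sdlog = 0.4),
    compendium_size = 200L, n_transcripts = 120L,
    epitope_sample_rate = epitope_sample_rate, rna_fraction = rna_fraction,
    seed = seed, ...)
}

# one ideal caller reporting the truth exactly, for noiseless-limit checks
noiseless_callers <- function(n = 3L) {
  data.table::data.table(
    caller = paste0("caller", seq_len(n)),
    sensitivity = 1, fp_rate = 0,
    classes = "SNV,insertion,deletion")
}

# single-type cohort for regression-model parameter recovery
recovery_config <- function(seed, n = 300L, beta = 0.5, hr_high = 1,
                            median_count = 60) {
  cohort_config(
    n_patients_per_type = c(melanoma = as.integer(n)),
    tmb_lognormal = list(melanoma = c(log(median_count), 1.0)),
    caller_models = noiseless_callers(1L),
    therapy_mix = list(melanoma = c(aPD1 = 1)),
    response_model = c(beta0 = -0.5 - beta * log2(median_count),
                       beta_log2 = beta, offset_aCTLA4 = 0),
    survival_model = c(baseline_hazard = log(2) / 600, hr_high_tmb = hr_high),
    response_missing_rate = 0, multi_sample_fraction = 0,
    rna_fraction = 0, epitope_sample_rate = 0,
    compendium_size = 10L, n_transcripts = 10L,
    seed = seed)
}
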