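test_that("the same seed reproduces the bundle bit-for-bit", {
  co1 <- generate_cohort(tiny_cohort_config(seed = 7L))
  co2 <- generate_cohort(tiny_cohort_config(seed = 7L))
  for (nm in c("patients", "calls", "truth_variants", "binding", "peptides",
               "junctions", "transcript_quants", "intron_counts")) {
    expect_identical(co1[[nm]], co2[[nm]], label = nm)
  }
  expect_identical(co1$truth, co2$truth)
  # a different seed moves the data
  co3 <- generate_cohort(tiny_cohort_config(seed = 8L))
  expect_false(identical(co1$patients$true_n_variants,
                         co3$patients$true_n_variants))
})

test_that("per-patient sub-seeds are stable under changes elsewhere in the config", {
  co_a <- generate_cohort(tiny_cohort_config(seed = 7L, n_mel = 6L, n_rcc = 0L))
  co_b <- generate_cohort(tiny_cohort_config(seed = 7L, n_mel = 6L, n_rcc = 5L))
  mel_a <- co_a$patients[co_a$patients$cancer_type == "melanoma", ]
  mel_b <- co_b$patients[co_b$patients$cancer_type == "melanoma", ]
  expect_identical(mel_a$true_n_variants, mel_b$true_n_variants)
  expect_identical(mel_a$therapy, mel_b$therapy)
})

test_that("noiseless callers reproduce the true variant set exactly", {
  cfg <- tiny_cohort_config(seed = 9L, n_mel = 6L, n_rcc = 0L,
                            caller_models = noiseless_callers(3L),
                            multi_sample_fraction = 0)
  co <- generate_cohort(cfg)
  for (pid in co$patients$patient) {
    truth_keys <- co$truth[[pid]]$true_variant_keys
    for (cl in cfg$caller_models$caller) {
      calls <- co$calls[co$calls$patient == pid & co$calls$caller == cl, ]
      keys <- paste(calls$chrom, calls$pos, calls$ref, calls$alt, sep = ":")
      expect_setequal(keys, truth_keys)
    }
  }
  # consequently every caller's TMB equals the truth and variability is 0
  res <- tmb_stage(co)
  expect_equal(res$cohort_variability, 0)
})

test_that("a zero burden coefficient makes response independent of burden", {
  co <- generate_cohort(recovery_config(seed = 101L, n = 300L, beta = 0))
  fit <- fit_response_model(co$patients$true_n_variants, co$patients$response)
  expect_lt(abs(fit$slope) / fit$se, 4)
  # all true response probabilities equal under the null
  expect_equal(length(unique(round(co$patients$true_response_prob, 12))), 1)
})

test_that("empirical response rate converges to the configured logistic mean", {
  co <- generate_cohort(recovery_config(seed = 102L, n = 400L, beta = 0.5))
  p_true <- co$patients$true_response_prob
  rate <- mean(co$patients$response)
  # binomial tolerance: 4 sd of the mean of independent Bernoullis
  tol <- 4 * sqrt(sum(p_true * (1 - p_true))) / length(p_true)
  expect_lt(abs(rate - mean(p_true)), tol)
})

test_that("invalid configuration fields are rejected by name", {
  expect_error(tiny_cohort_config(rna_fraction = 1.5), "rna_fraction")
  expect_error(tiny_cohort_config(seed = -1), "seed")
  expect_error(
    cohort_config(n_patients_per_type = c(melanoma = 5L),
                  tmb_lognormal = list(melanoma = c(log(10), -1))),
    "tmb_lognormal")
  bad_callers <- data.table::data.table(caller = "x", sensitivity = 1.4,
                                        fp_rate = 0, classes = "SNV")
  expect_error(tiny_cohort_config(caller_models = bad_callers),
               "caller_models")
})

test_that("coverage tracks reproduce each patient's covered Mbp at depth 6", {
  co <- generate_cohort(tiny_cohort_config(seed = 10L, n_mel = 5L, n_rcc = 0L))
  for (pid in co$patients$patient) {
    s1 <- co$samples$sample_id[co$samples$patient == pid][1]
    track <- co$coverage[co$coverage$patient == pid &
                           co$coverage$sample_id == s1, ]
    expect_equal(genome_coverage_mbp(track),
                 co$patients$mbp_covered[co$patients$patient == pid])
  }
})

test_that("synthetic proteome and variants are deterministic and bounded", {
  pv1 <- generate_proteome_and_variants(5, c(60, 120), 10, seed = 5L)
  pv2 <- generate_proteome_and_variants(5, c(60, 120), 10, seed = 5L)
  expect_identical(pv1, pv2)
  expect_equal(length(pv1$proteome), 5)
  expect_true(all(nchar(pv1$proteome) >= 60 & nchar(pv1$proteome) <= 120))
  expect_equal(nrow(pv1$variants), 10)
  # variant positions lie inside their protein
  lens <- nchar(pv1$proteome)[pv1$variants$protein_id]
  expect_true(all(pv1$variants$position >= 1 &
                    pv1$variants$position <= lens))
  # zero variants -> empty table; too many -> error
  expect_equal(nrow(generate_proteome_and_variants(2, c(30, 30), 0, 1L)$variants), 0)
  expect_error(generate_proteome_and_variants(1, c(30, 30), 31, 1L), "exceeds")
})

test_that("substitutions applied to the proteome flow through enumeration", {
  pv <- generate_proteome_and_variants(3, c(100, 100), 6, seed = 6L)
  subs <- pv$variants[pv$variants$vclass == "substitution", ]
  for (j in seq_len(nrow(subs))) {
    v <- subs[j]
    mut <- apply_protein_variant(pv$proteome[[v$protein_id]], v)
    res <- enumerate_snv_peptides(mut$sequence, mut$altered_position)
    orc <- oracle_windows(mut$sequence, mut$altered_position, 8:24)
    expect_equal(attr(res, "n_windows"), orc$n_windows)
    # interior substitutions far from both termini give the full 272
    if (v$position > 24 && v$position <= 100 - 24) {
      expect_equal(attr(res, "n_windows"), 272)
    }
  }
})
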