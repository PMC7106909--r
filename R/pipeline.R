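## End-to-end orchestration: consensus -> burdens -> RNA variants ->
## evaluation, over an in-memory cohort bundle (from generate_cohort() or
## read_cohort_bundle()).

.metric_cols <- c("tmb_raw", "tmb_adjusted", "tmb_x_hla", "hla_count",
                  "nb", "nb_A", "nb_M", "nb_T", "nb_E",
                  "nb_AM", "nb_AT", "nb_AE", "nb_MT", "nb_ME",
                  "nb_AMT", "nb_AME", "jx_burden", "ri_burden",
                  "ri_epitope_burden", "tvb")

#' Consensus TMB stage over a cohort
#'
#' Per sample: consensus variant set across callers and coverage-adjusted
#' TMB; per patient: the median across samples, per-caller counts, and the
#' cross-caller variability statistic.
#'
#' @param cohort a `tvb_cohort`.
#' @param params thresholds from [pipeline_params()].
#' @return list with `per_patient` (data.table), `per_caller_counts`
#'   (data.table patient x caller) and `cohort_variability`.
#' @export
tmb_stage <- function(cohort, params = pipeline_params()) {
  caller_classes <- stats::setNames(
    strsplit(cohort$config$caller_models$classes, ",", fixed = TRUE),
    cohort$config$caller_models$caller)
  per_sample <- list()
  per_caller <- list()
  for (pid in cohort$patients$patient) {
    samp_ids <- cohort$samples[patient == pid, sample_id]
    for (s in samp_ids) {
      calls_s <- cohort$calls[patient == pid & sample_id == s]
      sets <- split(calls_s[, .(chrom, pos, ref, alt)], calls_s$caller)
      if (length(sets) == 0L) sets <- list(none = data.table::data.table(
        chrom = character(), pos = integer(), ref = character(), alt = character()))
      cons <- consensus_variants(sets, min_callers = min(params$min_callers,
                                                         length(sets)),
                                 caller_classes = caller_classes[names(sets)])
      cov_s <- cohort$coverage[patient == pid & sample_id == s]
      mbp <- genome_coverage_mbp(cov_s, min_depth = params$min_depth)
      rec <- coverage_adjusted_tmb(nrow(cons), mbp)
      per_sample[[paste(pid, s)]] <- data.table::data.table(
        patient = pid, sample_id = s, raw_count = rec$raw_count,
        mbp_covered = rec$mbp_covered, adjusted = rec$adjusted)
      per_caller[[paste(pid, s)]] <- data.table::data.table(
        patient = pid, sample_id = s,
        caller = names(sets),
        count = vapply(sets, function(x)
          nrow(unique(normalize_variants(x),
                      by = c("chrom", "pos", "ref", "alt"))), integer(1)))
    }
  }
  per_sample <- data.table::rbindlist(per_sample)
  per_caller <- data.table::rbindlist(per_caller)
  per_patient <- per_sample[, .(
    tmb_raw = as.numeric(aggregate_multisample(raw_count)),
    tmb_adjusted = as.numeric(aggregate_multisample(adjusted)),
    mbp_covered = as.numeric(aggregate_multisample(mbp_covered))
  ), by = patient]
  caller_counts <- per_caller[, .(count = as.numeric(aggregate_multisample(count))),
                              by = .(patient, caller)]
  variability <- caller_counts[, {
    v <- count
    ok <- length(v) >= 2L && stats::median(v) > 0
    .(caller_variability = if (ok) caller_variability(stats::setNames(v, caller)) else NA_real_,
      range_fraction = if (ok) tmb_range_fraction(stats::setNames(v, caller))$fraction_of_median else NA_real_)
  }, by = patient]
  per_patient <- merge(per_patient, variability, by = "patient", sort = FALSE)
  list(per_patient = per_patient,
       per_caller_counts = caller_counts,
       cohort_variability = cohort_variability(
         per_patient[!is.na(caller_variability), caller_variability]))
}

#' Neoepitope burden stage over a cohort
#'
#' Calls binders per patient at the affinity threshold, assembles epitope
#' weight components (A, M, T and, for RNA patients, E), and computes the
#' raw and weighted burden family.
#'
#' @param cohort a `tvb_cohort`.
#' @param params thresholds from [pipeline_params()].
#' @return data.table, one row per patient, burden columns.
#' @export
burden_stage <- function(cohort, params = pipeline_params()) {
  combos <- list(nb = character(0), nb_A = "A", nb_M = "M", nb_T = "T",
                 nb_E = "E", nb_AM = c("A", "M"), nb_AT = c("A", "T"),
                 nb_AE = c("A", "E"), nb_MT = c("M", "T"),
                 nb_ME = c("M", "E"), nb_AMT = c("A", "M", "T"),
                 nb_AME = c("A", "M", "E"))
  rows <- lapply(cohort$patients$patient, function(pid) {
    alleles <- cohort$hla[patient == pid, allele]
    has_rna <- cohort$patients[patient == pid, has_rna]
    recs <- cohort$binding[patient == pid]
    peps <- cohort$peptides[patient == pid]
    bm <- call_binders(recs, alleles, threshold_nm = params$affinity_threshold_nm)
    ecov <- NULL
    if (isTRUE(has_rna) && nrow(cohort$exon_coverage) > 0L) {
      ec <- cohort$exon_coverage[patient == pid]
      if (nrow(ec)) ecov <- stats::setNames(ec$max_reads, ec$transcript)
    }
    w <- epitope_weights(peps, bm, cohort$tcga_quantiles, exon_coverage = ecov)
    vals <- lapply(combos, function(comp) {
      if (any(c("E") %in% comp) && is.null(ecov)) return(NA_real_)
      as.numeric(weighted_burden(w, comp))
    })
    data.table::as.data.table(c(list(patient = pid), vals))
  })
  data.table::rbindlist(rows)
}

#' RNA variant stage: tumor-specific junctions and retained introns
#'
#' Junctions: filters each RNA patient's junction table against the normal
#' compendium and the annotation rules. Retained introns: applies the
#' transcript expression filters cohort-wide, the per-transcript MAD outlier
#' rule per patient, and subtracts retained introns found in the normal
#' (melanocyte) samples; enumerates intron-encoded peptides where intron
#' sequences are available.
#'
#' @param cohort a `tvb_cohort`.
#' @param params thresholds from [pipeline_params()].
#' @return data.table per patient: jx_burden, ri_burden, ri_epitope_burden
#'   (NA for patients without the corresponding RNA data).
#' @export
rna_stage <- function(cohort, params = pipeline_params()) {
  out <- data.table::data.table(patient = cohort$patients$patient,
                                jx_burden = NA_real_, ri_burden = NA_real_,
                                ri_epitope_burden = NA_real_)
  compendium <- build_compendium(list(cohort$normal_junctions))
  rna_pats <- cohort$patients[has_rna == TRUE, patient]
  for (pid in rna_pats) {
    jx <- cohort$junctions[patient == pid]
    if (nrow(jx)) {
      ts <- tumor_specific_junctions(jx, compendium)
      out[patient == pid, jx_burden := as.numeric(junction_burden(ts))]
    } else if (pid %in% cohort$junctions$patient || nrow(cohort$junctions) > 0L) {
      out[patient == pid, jx_burden := 0]
    }
  }
  ## retained introns (patients with intron count data)
  if (nrow(cohort$intron_counts) > 0L) {
    kept_tx <- filter_transcripts(cohort$transcript_quants,
                                  tpm_min = params$tpm_min,
                                  count_min = params$count_min,
                                  sample_frac = params$sample_frac)
    normal_ris <- character(0)
    if (!is.null(cohort$normal_intron_counts) &&
        nrow(cohort$normal_intron_counts) > 0L) {
      normal_ris <- detect_ris(cohort$normal_intron_counts, kept_tx,
                               mad_multiplier = params$mad_multiplier)
    }
    for (pid in intersect(rna_pats, unique(cohort$intron_counts$patient))) {
      tumor_ris <- detect_ris(cohort$intron_counts[patient == pid], kept_tx,
                              mad_multiplier = params$mad_multiplier)
      final_ris <- subtract_normal_ris(tumor_ris, normal_ris)
      out[patient == pid, ri_burden := as.numeric(length(final_ris))]
      out[patient == pid,
          ri_epitope_burden := as.numeric(.ri_epitope_count(cohort, final_ris))]
    }
  }
  out
}

#' Detect retained introns in one sample's intron count table
#'
#' Applies the MAD outlier rule per transcript, restricted to transcripts
#' passing the expression filters.
#'
#' @param intron_counts data.table with columns transcript, intron_index,
#'   count, transcript_count.
#' @param kept_transcripts transcripts passing [filter_transcripts()].
#' @param mad_multiplier MAD multiplier (default 3).
#' @return character vector of RI keys ("transcript:intron_index").
#' @export
detect_ris <- function(intron_counts, kept_transcripts, mad_multiplier = 3) {
  dt <- data.table::as.data.table(intron_counts)
  dt <- dt[transcript %in% kept_transcripts]
  if (nrow(dt) == 0L) return(character(0))
  hits <- dt[, {
    idx <- intron_outlier_filter(count, transcript_count[1L],
                                 mad_multiplier = mad_multiplier)
    .(intron_index = intron_index[idx])
  }, by = transcript]
  if (nrow(hits) == 0L) return(character(0))
  paste(hits$transcript, hits$intron_index, sep = ":")
}

.ri_epitope_count <- function(cohort, ri_keys) {
  if (length(ri_keys) == 0L) return(0L)
  seqs <- cohort$intron_seqs
  if (is.null(seqs) || nrow(seqs) == 0L) return(0L)
  total <- 0L
  for (k in ri_keys) {
    parts <- strsplit(k, ":", fixed = TRUE)[[1]]
    row <- seqs[transcript == parts[1] & intron_index == as.integer(parts[2])]
    if (nrow(row) == 0L) next
    pep <- ri_peptides(row$upstream_cds[1L], row$intron_seq[1L])
    total <- total + attr(pep, "n_distinct")
  }
  total
}

#' Assemble the patient x metric burden table
#'
#' @param cohort a `tvb_cohort`.
#' @param params thresholds from [pipeline_params()].
#' @return data.table, one row per patient, with clinical columns and all
#'   burden metrics. TVB is the exact sum of the consensus variant count and
#'   the junction and retained-intron burdens, defined for patients with RNA.
#' @export
burden_table <- function(cohort, params = pipeline_params()) {
  tmb <- tmb_stage(cohort, params)
  nb <- burden_stage(cohort, params)
  rna <- rna_stage(cohort, params)
  bt <- Reduce(function(a, b) merge(a, b, by = "patient", sort = FALSE),
               list(cohort$patients[, .(patient, cancer_type, therapy, response,
                                        os_time, os_event, has_rna, n_unique_hla)],
                    tmb$per_patient, nb, rna))
  bt[, hla_count := n_unique_hla]
  bt[, tmb_x_hla := tmb_raw * n_unique_hla]
  bt[, tvb := data.table::fifelse(
    is.na(jx_burden) | is.na(ri_burden), NA_real_,
    tmb_raw + jx_burden + ri_burden)]
  ## patients with junction data but no intron data: RI component counts 0
  bt[is.na(tvb) & !is.na(jx_burden),
     tvb := tmb_raw + jx_burden + data.table::fifelse(is.na(ri_burden), 0, ri_burden)]
  data.table::setattr(bt, "cohort_variability", tmb$cohort_variability)
  data.table::setattr(bt, "per_caller_counts", tmb$per_caller_counts)
  bt[]
}

#' Evaluate burden metrics as predictors of response and survival
#'
#' Per cohort (each cancer type plus the pooled "all" cohort): ROC AUC for
#' every metric; logistic response models (single-agent therapy only, with a
#' therapy covariate where two arms exist) for TMB, neoepitope burden and
#' TVB, BH-adjusted within each cohort; survival stratification at the
#' disease-matched percentile with a Cox fit and a threshold sweep.
#'
#' @param bt a [burden_table()].
#' @param params thresholds from [pipeline_params()].
#' @param survival_types cancer types with enough events for survival
#'   analysis (default melanoma and RCC).
#' @return list of class `tvb_report` with `auc`, `response_models`,
#'   `survival`, `sweeps`, `cohort_variability`.
#' @export
evaluate_burdens <- function(bt, params = pipeline_params(),
                             survival_types = c("melanoma", "RCC")) {
  bt <- data.table::as.data.table(bt)
  cohorts <- c(list(all = bt), split(bt, bt$cancer_type))
  metrics <- intersect(.metric_cols, names(bt))
  auc_rows <- list(); resp_rows <- list(); surv <- list(); sweeps <- list()
  for (cname in names(cohorts)) {
    cb <- cohorts[[cname]]
    eval_resp <- cb[!is.na(response) & therapy %in% c("aPD1", "aCTLA4")]
    if (length(unique(eval_resp$response)) == 2L) {
      for (m in metrics) {
        ok <- !is.na(eval_resp[[m]])
        if (sum(ok) < 10L || length(unique(eval_resp$response[ok])) < 2L) next
        r <- roc_auc(eval_resp[[m]][ok], eval_resp$response[ok], metric = m)
        auc_rows[[paste(cname, m)]] <- data.table::data.table(
          cohort = cname, metric = m, auc = r$auc, n = sum(ok))
      }
      for (m in intersect(c("tmb_raw", "nb", "tvb"), metrics)) {
        ok <- !is.na(eval_resp[[m]])
        if (sum(ok) < 10L) next
        therapy_arg <- if (length(unique(eval_resp$therapy[ok])) >= 2L)
          eval_resp$therapy[ok] else NULL
        fit <- tryCatch(
          fit_response_model(eval_resp[[m]][ok], eval_resp$response[ok],
                             therapy = therapy_arg,
                             pseudocount = params$pseudocount),
          error = function(e) NULL)
        if (is.null(fit)) next
        resp_rows[[paste(cname, m)]] <- data.table::data.table(
          cohort = cname, metric = m, n = fit$n, slope = fit$slope,
          odds_increase_pct = fit$odds_increase_pct, p_value = fit$p_value,
          response_prob_q25 = fit$response_prob_q25,
          response_prob_q75 = fit$response_prob_q75,
          separation = fit$separation)
      }
    }
    if (cname %in% survival_types && nrow(cb) >= 10L) {
      hl <- classify_high_low(cb$tmb_adjusted, params$percentile)
      sf <- tryCatch(fit_survival(cb, hl), error = function(e) NULL)
      if (!is.null(sf)) surv[[cname]] <- sf
      sweeps[[cname]] <- tryCatch(
        threshold_sweep(cb, cb$tmb_adjusted), error = function(e) NULL)
    }
  }
  resp <- data.table::rbindlist(resp_rows)
  if (nrow(resp)) resp[, p_adjusted := bh_adjust(p_value), by = cohort]
  structure(list(auc = data.table::rbindlist(auc_rows),
                 response_models = resp, survival = surv, sweeps = sweeps,
                 cohort_variability = attr(bt, "cohort_variability")),
            class = "tvb_report")
}

#' @export
print.tvb_report <- function(x, ...) {
  cat("Tumor variant burden evaluation report\n")
  if (!is.null(x$cohort_variability))
    cat(sprintf("  cohort caller variability (median): %.3f\n", x$cohort_variability))
  cat(sprintf("  AUC entries: %d; response models: %d; survival cohorts: %s\n",
              nrow(x$auc), nrow(x$response_models),
              paste(names(x$survival), collapse = ", ")))
  invisible(x)
}

#' Run the full pipeline on a cohort bundle
#'
#' Consensus TMB -> neoepitope burdens -> RNA variant burdens -> burden table
#' -> evaluation. Stages touching missing inputs (e.g. no RNA data) are
#' skipped with a warning, producing DNA-only metrics.
#'
#' @param cohort a `tvb_cohort` (from [generate_cohort()] or
#'   [read_cohort_bundle()]).
#' @param params thresholds from [pipeline_params()].
#' @param out_dir optional directory; when given, all result tables are
#'   written there as TSV and the report summary as JSON.
#' @return list with `burden_table` and `report`.
#' @export
run_pipeline <- function(cohort, params = pipeline_params(), out_dir = NULL) {
  .assert(inherits(cohort, "tvb_cohort"), "`cohort` must be a tvb_cohort")
  if (!any(cohort$patients$has_rna)) {
    warning("no patients with RNA data: junction/RI stages skipped, DNA-only metrics produced",
            call. = FALSE)
  }
  bt <- burden_table(cohort, params)
  report <- evaluate_burdens(bt, params)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    .write_tsv <- function(x, f) data.table::fwrite(x, file.path(out_dir, f),
                                                    sep = "\t")
    .write_tsv(bt, "burden_table.tsv")
    if (nrow(report$auc)) .write_tsv(report$auc, "auc.tsv")
    if (nrow(report$response_models)) .write_tsv(report$response_models,
                                                 "response_models.tsv")
    summary <- list(
      n_patients = nrow(bt),
      cohort_variability = report$cohort_variability,
      survival = lapply(report$survival, function(s)
        list(hazard_ratio = s$hazard_ratio, p_value = s$p_value,
             n = s$n, n_events = s$n_events, flag = s$flag)))
    jsonlite::write_json(summary, file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
  }
  list(burden_table = bt, report = report)
}
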