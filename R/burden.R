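## Binder calling and the family of raw / weighted / combined burden metrics.

#' Call high-affinity MHC binders
#'
#' An allele counts as binding a peptide when the predicted affinity is at
#' most `threshold_nm` (inclusive, default 500 nM) and the allele belongs to
#' the patient's genotype. Records referencing alleles outside the patient's
#' set are skipped with a warning.
#'
#' @param records data.frame of binding records (peptide, allele, affinity_nm).
#' @param patient_alleles character vector of the patient's HLA alleles.
#' @param threshold_nm inclusive affinity threshold in nM (default 500).
#' @return named list mapping each peptide with at least one binding allele to
#'   the character vector of its binding alleles.
#' @export
call_binders <- function(records, patient_alleles, threshold_nm = 500) {
  .assert(is.numeric(threshold_nm) && threshold_nm > 0,
          "`threshold_nm` must be > 0")
  dt <- data.table::as.data.table(records)
  if (nrow(dt) == 0L) return(stats::setNames(list(), character(0)))
  .assert(all(c("peptide", "allele", "affinity_nm") %in% names(dt)),
          "binding records need columns peptide, allele, affinity_nm")
  .assert(all(dt$affinity_nm > 0), "affinities must be positive (nM)")
  foreign <- !(dt$allele %in% patient_alleles)
  if (any(foreign)) {
    warning(sprintf("skipping %d binding record(s) for alleles outside the patient genotype",
                    sum(foreign)), call. = FALSE)
    dt <- dt[!foreign]
  }
  binders <- dt[affinity_nm <= threshold_nm]
  if (nrow(binders) == 0L) return(stats::setNames(list(), character(0)))
  lapply(split(binders$allele, binders$peptide), unique)
}

#' Raw neoepitope burden
#'
#' Number of distinct peptides bound by at least one patient MHC allele.
#'
#' @param binder_map output of [call_binders()].
#' @return integer count.
#' @export
raw_neoepitope_burden <- function(binder_map) {
  sum(lengths(binder_map) >= 1L)
}

#' Weighted neoepitope burden
#'
#' Each epitope contributes the product of its requested weight components:
#' A (number of patient alleles binding it), M (amino-acid mismatches to the
#' closest normal peptide), T (TCGA-expressed transcripts of origin) and E
#' (patient-expressed transcripts of origin; requires patient RNA). The burden
#' is the sum of epitope scores. With an empty component set the raw burden
#' (count of epitopes with A >= 1) is returned.
#'
#' @param epitopes data.frame with integer columns among A, M, T, E.
#' @param components character subset of c("A", "M", "T", "E").
#' @return the burden (a single number).
#' @export
weighted_burden <- function(epitopes, components = character(0)) {
  dt <- data.table::as.data.table(epitopes)
  .assert(all(components %in% c("A", "M", "T", "E")),
          "components must be a subset of A, M, T, E")
  if (length(components) == 0L) {
    .assert("A" %in% names(dt), "raw burden needs the A component")
    return(sum(dt$A >= 1L))
  }
  missing_cols <- setdiff(components, names(dt))
  .assert(length(missing_cols) == 0L,
          paste0("epitopes lack requested component(s): ",
                 paste(missing_cols, collapse = ", ")))
  if ("E" %in% components && anyNA(dt$E)) {
    stop("component E requested but patient RNA expression is unavailable",
         call. = FALSE)
  }
  if (nrow(dt) == 0L) return(0)
  prod_terms <- rep(1, nrow(dt))
  for (comp in components) prod_terms <- prod_terms * dt[[comp]]
  sum(prod_terms)
}

#' TCGA expression weight (T) for an epitope
#'
#' Counts the transcripts of origin whose disease-matched 75th-quantile TPM in
#' TCGA is strictly greater than 1. Transcripts missing from the quantile
#' table are treated as unexpressed.
#'
#' @param transcripts_of_origin character vector of transcript ids.
#' @param tcga_tpm_quantiles named numeric vector (transcript -> 75th-quantile
#'   TPM) or a data.frame with columns transcript, q75_tpm.
#' @return integer T weight.
#' @export
tcga_expression_weight <- function(transcripts_of_origin, tcga_tpm_quantiles) {
  if (is.data.frame(tcga_tpm_quantiles)) {
    tcga_tpm_quantiles <- stats::setNames(tcga_tpm_quantiles$q75_tpm,
                                          tcga_tpm_quantiles$transcript)
  }
  if (length(transcripts_of_origin) == 0L) return(0L)
  q <- tcga_tpm_quantiles[transcripts_of_origin]
  q[is.na(q)] <- 0
  sum(q > 1)
}

#' Patient expression weight (E) for an epitope
#'
#' Counts the transcripts of origin with at least one RNA-seq read covering
#' any exon of the transcript in the patient's tumor.
#'
#' @param transcripts_of_origin character vector of transcript ids.
#' @param exon_coverage named numeric vector (transcript -> maximum reads on
#'   any exon) for the patient; `NULL` means no RNA data.
#' @return integer E weight.
#' @export
patient_expression_weight <- function(transcripts_of_origin, exon_coverage) {
  if (is.null(exon_coverage)) {
    stop("patient expression weight requires patient RNA coverage data",
         call. = FALSE)
  }
  if (length(transcripts_of_origin) == 0L) return(0L)
  cov <- exon_coverage[transcripts_of_origin]
  cov[is.na(cov)] <- 0
  sum(cov >= 1)
}

#' Tumor variant burden (TVB)
#'
#' The exact sum of somatic variants, tumor-specific splice junctions, and
#' tumor-specific retained introns.
#'
#' @param n_somatic,n_jx,n_ri non-negative integer component counts.
#' @return integer TVB.
#' @export
tumor_variant_burden <- function(n_somatic, n_jx, n_ri) {
  .assert(.is_count(n_somatic) && .is_count(n_jx) && .is_count(n_ri),
          "all TVB components must be non-negative integers")
  as.integer(n_somatic + n_jx + n_ri)
}

#' TMB multiplied by unique patient HLA allele count
#'
#' @param tmb TMB value (raw or coverage-adjusted).
#' @param n_unique_hla number of unique HLA alleles in the patient genotype.
#' @return the product.
#' @export
tmb_times_hla <- function(tmb, n_unique_hla) {
  .assert(.is_count(n_unique_hla), "`n_unique_hla` must be a non-negative integer")
  .assert(is.numeric(tmb) && length(tmb) == 1L && tmb >= 0, "`tmb` must be >= 0")
  tmb * n_unique_hla
}

#' Assemble per-epitope weight components for one patient
#'
#' Convenience builder joining the binder map (A), planted or computed
#' mismatch counts (M), TCGA expression (T) and, when available, patient
#' expression (E) into the epitope weight table consumed by
#' [weighted_burden()].
#'
#' @param peptides data.frame with columns peptide, mismatches and a
#'   comma-separated `transcripts` column of transcripts of origin.
#' @param binder_map output of [call_binders()] for the patient.
#' @param tcga_tpm_quantiles table for [tcga_expression_weight()].
#' @param exon_coverage patient table for [patient_expression_weight()], or
#'   `NULL` when the patient has no RNA (E becomes NA).
#' @return data.table with one row per distinct peptide and columns A, M, T, E.
#' @export
epitope_weights <- function(peptides, binder_map, tcga_tpm_quantiles,
                            exon_coverage = NULL) {
  dt <- unique(data.table::as.data.table(peptides), by = "peptide")
  if (nrow(dt) == 0L) {
    return(data.table::data.table(peptide = character(), A = integer(),
                                  M = integer(), T = integer(), E = integer()))
  }
  tx_list <- strsplit(dt$transcripts, ",", fixed = TRUE)
  dt[, A := as.integer(lengths(binder_map[peptide]))]
  dt[is.na(A), A := 0L]
  dt[, M := as.integer(mismatches)]
  dt[, T := vapply(tx_list, tcga_expression_weight, integer(1),
                   tcga_tpm_quantiles = tcga_tpm_quantiles)]
  if (is.null(exon_coverage)) {
    dt[, E := NA_integer_]
  } else {
    dt[, E := vapply(tx_list, patient_expression_weight, integer(1),
                     exon_coverage = exon_coverage)]
  }
  dt[, .(peptide, A, M, T, E)]
}
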