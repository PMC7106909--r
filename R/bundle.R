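## Disk round-trip of a cohort bundle in standard formats: per-caller VCFs,
## coverage BED, junction tables, TSV quantifications and clinical tables,
## plus a JSON truth file and the YAML configuration.

.tsv_tables <- c("patients", "samples", "hla", "binding", "peptides",
                 "tcga_quantiles", "junctions", "normal_junctions",
                 "transcript_quants", "intron_counts",
                 "normal_intron_counts", "exon_coverage", "intron_seqs")

#' Write a cohort bundle to disk
#'
#' Variant calls are written as one VCF per patient/sample/caller, coverage
#' as BED depth tracks, and all other tables as TSV; the generating truth
#' goes to `truth.json` and the configuration to `config.yaml`.
#'
#' @param cohort a `tvb_cohort`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort_bundle <- function(cohort, dir) {
  dir.create(file.path(dir, "vcf"), recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "coverage"), showWarnings = FALSE)
  for (nm in .tsv_tables) {
    tb <- cohort[[nm]]
    if (!is.null(tb) && nrow(tb) > 0L) {
      data.table::fwrite(tb, file.path(dir, paste0(nm, ".tsv")), sep = "\t")
    }
  }
  if (nrow(cohort$calls)) {
    grp <- cohort$calls[, .(patient = patient[1L]), by = .(patient_key = paste(
      patient, sample_id, caller, sep = "__"))]
    for (k in grp$patient_key) {
      parts <- strsplit(k, "__", fixed = TRUE)[[1]]
      sub <- cohort$calls[patient == parts[1] & sample_id == parts[2] &
                            caller == parts[3]]
      write_vcf_calls(sub, file.path(dir, "vcf", paste0(k, ".vcf")))
    }
  }
  truth_vcf_dir <- file.path(dir, "vcf_truth")
  dir.create(truth_vcf_dir, showWarnings = FALSE)
  for (pid in unique(cohort$truth_variants$patient)) {
    write_vcf_calls(cohort$truth_variants[patient == pid],
                    file.path(truth_vcf_dir, paste0(pid, ".vcf")))
  }
  for (key in unique(cohort$coverage[, paste(patient, sample_id, sep = "__")])) {
    parts <- strsplit(key, "__", fixed = TRUE)[[1]]
    write_coverage_bed(cohort$coverage[patient == parts[1] & sample_id == parts[2],
                                       .(chrom, start, end, depth)],
                       file.path(dir, "coverage", paste0(key, ".bed")))
  }
  jsonlite::write_json(cohort$truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  write_config(cohort$config, file.path(dir, "config.yaml"))
  invisible(dir)
}

#' Read a cohort bundle from disk
#'
#' Reconstructs the in-memory cohort from a directory written by
#' [write_cohort_bundle()]; variant calls are re-read from the per-caller
#' VCFs (and re-normalized in the process).
#'
#' @param dir bundle directory.
#' @return a `tvb_cohort`.
#' @export
read_cohort_bundle <- function(dir) {
  .assert(dir.exists(dir), paste0("bundle directory not found: ", dir))
  out <- list(config = read_config(file.path(dir, "config.yaml")))
  for (nm in .tsv_tables) {
    f <- file.path(dir, paste0(nm, ".tsv"))
    out[[nm]] <- if (file.exists(f)) data.table::fread(f, sep = "\t")
    else data.table::data.table()
  }
  vcfs <- list.files(file.path(dir, "vcf"), pattern = "\\.vcf$",
                     full.names = TRUE)
  calls <- lapply(vcfs, function(f) {
    parts <- strsplit(sub("\\.vcf$", "", basename(f)), "__", fixed = TRUE)[[1]]
    dt <- read_vcf_calls(f)
    if (nrow(dt)) dt[, `:=`(patient = parts[1], sample_id = parts[2],
                            caller = parts[3])]
    dt
  })
  out$calls <- data.table::rbindlist(Filter(function(x) nrow(x) > 0L, calls))
  tvcfs <- list.files(file.path(dir, "vcf_truth"), pattern = "\\.vcf$",
                      full.names = TRUE)
  tvars <- lapply(tvcfs, function(f) {
    dt <- read_vcf_calls(f)
    if (nrow(dt)) dt[, patient := sub("\\.vcf$", "", basename(f))]
    dt
  })
  out$truth_variants <- data.table::rbindlist(Filter(function(x) nrow(x) > 0L,
                                                     tvars))
  beds <- list.files(file.path(dir, "coverage"), pattern = "\\.bed$",
                     full.names = TRUE)
  cov <- lapply(beds, function(f) {
    parts <- strsplit(sub("\\.bed$", "", basename(f)), "__", fixed = TRUE)[[1]]
    dt <- read_coverage_bed(f)
    dt[, `:=`(patient = parts[1], sample_id = parts[2])]
    dt
  })
  out$coverage <- data.table::rbindlist(cov)
  out$truth <- jsonlite::read_json(file.path(dir, "truth.json"),
                                   simplifyVector = TRUE)
  structure(out, class = "tvb_cohort")
}

#' @export
print.tvb_cohort <- function(x, ...) {
  cat(sprintf("Synthetic tumor cohort: %d patients (%s); %d with RNA-seq\n",
              nrow(x$patients),
              paste(sprintf("%d %s", table(x$patients$cancer_type),
                            names(table(x$patients$cancer_type))),
                    collapse = ", "),
              sum(x$patients$has_rna)))
  invisible(x)
}
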