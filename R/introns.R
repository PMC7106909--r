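## Retained-intron detection: transcript expression filters, the MAD outlier
## rule on intron read counts, normal-tissue subtraction, and translation of
## intron-encoded peptides.

#' Transcript-level expression filters for intron-retention analysis
#'
#' A transcript is retained when (1) it reaches >= `tpm_min` TPM in at least
#' `sample_frac` of samples, (2) it has >= `count_min` unique counts in at
#' least `sample_frac` of samples, and (3) its mean intron-retention fraction
#' across samples is strictly between 0 and 1 (transcripts with no retention
#' carry no signal; transcripts fully retained everywhere are unprocessed-RNA
#' artifacts).
#'
#' @param quants long data.frame with columns transcript, sample_id, tpm,
#'   unique_counts, retention_frac.
#' @param tpm_min TPM threshold (default 1, inclusive).
#' @param count_min unique-count threshold (default 5, inclusive).
#' @param sample_frac required fraction of samples (default 0.25, inclusive).
#' @return character vector of retained transcript ids.
#' @export
filter_transcripts <- function(quants, tpm_min = 1, count_min = 5,
                               sample_frac = 0.25) {
  dt <- data.table::as.data.table(quants)
  .assert(nrow(dt) >= 1L, "empty quantification table")
  need <- c("transcript", "tpm", "unique_counts", "retention_frac")
  .assert(all(need %in% names(dt)),
          paste0("quants needs columns: ", paste(need, collapse = ", ")))
  .assert(all(dt$retention_frac >= 0 & dt$retention_frac <= 1),
          "retention_frac must lie in [0, 1]")
  stats <- dt[, .(
    frac_tpm = mean(tpm >= tpm_min),
    frac_counts = mean(unique_counts >= count_min),
    mean_ret = mean(retention_frac)
  ), by = transcript]
  stats[frac_tpm >= sample_frac & frac_counts >= sample_frac &
          mean_ret > 0 & mean_ret < 1, transcript]
}

#' MAD outlier filter on intron read counts within a transcript
#'
#' An intron is called retained when its read count is strictly greater than
#' the median intron read count plus `mad_multiplier` median absolute
#' deviations (unscaled MAD by default: no 1.4826 normal-consistency factor),
#' and at least the read count of the transcript itself. Both conditions as
#' stated exclude unprocessed-transcript artifacts.
#'
#' @param intron_counts numeric vector of per-intron read counts for one
#'   transcript (one sample).
#' @param transcript_count the transcript's own read count in that sample.
#' @param mad_multiplier number of MADs above the median (default 3).
#' @param scaled if TRUE, use the normal-consistency scaled MAD (for
#'   sensitivity analysis); default FALSE.
#' @return integer indices of retained introns.
#' @export
intron_outlier_filter <- function(intron_counts, transcript_count,
                                  mad_multiplier = 3, scaled = FALSE) {
  .assert(is.numeric(intron_counts) && length(intron_counts) >= 1L,
          "need at least one intron count")
  .assert(all(intron_counts >= 0), "intron read counts must be >= 0")
  const <- if (scaled) 1.4826 else 1
  med <- stats::median(intron_counts)
  spread <- stats::mad(intron_counts, constant = const)
  which(intron_counts > med + mad_multiplier * spread &
          intron_counts >= transcript_count)
}

#' Subtract normal-tissue retained introns from a tumor RI set
#'
#' Set difference on the retained-intron identity key. Accepts either
#' character key vectors or data.frames with columns transcript and
#' intron_index.
#'
#' @param tumor_ris tumor retained-intron set.
#' @param normal_ris normal-tissue retained-intron set.
#' @return tumor RIs absent from the normal set (same representation as the
#'   tumor input).
#' @export
subtract_normal_ris <- function(tumor_ris, normal_ris) {
  as_keys <- function(x) {
    if (is.data.frame(x)) paste(x$transcript, x$intron_index, sep = ":")
    else as.character(x)
  }
  keep <- !(as_keys(tumor_ris) %in% as_keys(normal_ris))
  if (is.data.frame(tumor_ris)) data.table::as.data.table(tumor_ris)[keep]
  else tumor_ris[keep]
}

.translate_nt <- function(nt) {
  nt <- toupper(nt)
  n_codons <- nchar(nt) %/% 3L
  if (n_codons == 0L) return("")
  codons <- substring(nt, 3L * seq_len(n_codons) - 2L, 3L * seq_len(n_codons))
  ambiguous <- grepl("[^ACGT]", codons)
  if (any(ambiguous)) {
    warning("ambiguous nucleotide encountered; translation stops at the first ambiguous codon",
            call. = FALSE)
    n_codons <- which(ambiguous)[1L] - 1L
    if (n_codons == 0L) return("")
    codons <- codons[seq_len(n_codons)]
  }
  aa <- as.character(Biostrings::translate(
    Biostrings::DNAString(paste(codons, collapse = "")), no.init.codon = TRUE))
  aa
}

#' Enumerate peptides encoded by a retained intron
#'
#' Translates across the exon-intron boundary in the reading frame
#' established by the upstream coding sequence (from the 5' end of the
#' transcript), until the first in-frame stop codon or the end of the intron.
#' Enumerates all windows of the requested lengths that contain at least one
#' intron-encoded (novel) residue; flanking residues come from the upstream
#' protein context.
#'
#' @param upstream_coding_sequence in-frame coding nucleotide sequence up to
#'   the intron start (frame 0 at its first base).
#' @param intron_sequence nucleotide sequence of the retained intron.
#' @param lengths integer vector of peptide lengths (default 8:24).
#' @return a data.table of distinct peptides as in
#'   [enumerate_snv_peptides()], with attributes n_windows, n_distinct.
#' @export
ri_peptides <- function(upstream_coding_sequence, intron_sequence,
                        lengths = 8:24) {
  up_len <- nchar(upstream_coding_sequence)
  full <- paste0(upstream_coding_sequence, intron_sequence)
  aa <- .translate_nt(full)
  u_full <- up_len %/% 3L  # codons wholly within the upstream exon(s)
  stop_at <- regexpr("*", aa, fixed = TRUE)
  if (stop_at > 0L) aa <- substring(aa, 1L, stop_at - 1L)
  if (nchar(aa) <= u_full) {
    # stop (or sequence end) reached before any intron-encoded residue
    return(.collapse_windows(list()))
  }
  context <- substring(aa, 1L, u_full)
  novel <- substring(aa, u_full + 1L)
  enumerate_frameshift_peptides(novel, context, lengths)
}
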