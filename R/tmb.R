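## Consensus TMB: multi-caller consensus sets, coverage-adjusted burden,
## and cross-caller instability statistics.

#' Consensus somatic variants across callers
#'
#' A variant is retained when its normalized identity key (chrom, pos, ref,
#' alt) is reported by at least `min_callers` callers. Because some callers
#' only emit certain variant classes (e.g. indel-only callers), consensus can
#' be computed per variant class over the callers declared to emit that class
#' via `caller_classes`; by default every caller is eligible for every class.
#'
#' @param per_caller_sets named list, one variant data.frame per caller
#'   (columns chrom, pos, ref, alt; normalized internally).
#' @param min_callers minimum number of supporting callers (default 2).
#' @param caller_classes optional named list mapping caller name to the
#'   variant classes ("SNV", "insertion", "deletion") it emits.
#' @return a data.table of consensus variants with a `callers` column listing
#'   the supporting callers (comma-separated) and `n_callers`.
#' @export
consensus_variants <- function(per_caller_sets, min_callers = 2L,
                               caller_classes = NULL) {
  .assert(is.list(per_caller_sets) && length(per_caller_sets) >= 1L,
          "`per_caller_sets` must be a non-empty named list of caller call sets")
  .assert(!is.null(names(per_caller_sets)) && all(nzchar(names(per_caller_sets))),
          "`per_caller_sets` must be named by caller")
  k <- length(per_caller_sets)
  .assert(.is_count(min_callers) && min_callers >= 1L && min_callers <= k,
          "`min_callers` must be between 1 and the number of callers")
  norm <- lapply(per_caller_sets, normalize_variants)
  all_calls <- data.table::rbindlist(
    lapply(names(norm), function(cl) {
      dt <- unique(norm[[cl]], by = c("chrom", "pos", "ref", "alt"))
      if (nrow(dt)) dt[, caller := cl]
      dt
    }), fill = TRUE)
  if (nrow(all_calls) == 0L) {
    return(data.table::data.table(chrom = character(), pos = integer(),
                                  ref = character(), alt = character(),
                                  vclass = character(), callers = character(),
                                  n_callers = integer()))
  }
  if (!is.null(caller_classes)) {
    keep <- mapply(function(cl, vc) vc %in% caller_classes[[cl]],
                   all_calls$caller, all_calls$vclass)
    all_calls <- all_calls[keep]
  }
  cons <- all_calls[, .(callers = paste(sort(caller), collapse = ","),
                        n_callers = .N),
                    by = .(chrom, pos, ref, alt, vclass)]
  cons <- cons[n_callers >= min_callers]
  data.table::setorder(cons, chrom, pos, ref, alt)
  cons[]
}

#' Megabases of genome covered at a minimum depth
#'
#' Sums the lengths of depth-track intervals whose depth is at least
#' `min_depth` (default 6 reads, i.e. twice the minimum depth required for
#' variant detection by the least sensitive callers) and reports the total in
#' Mbp.
#'
#' @param depth_track data.frame with 1-based closed columns chrom, start,
#'   end, depth (see [read_coverage_bed()]).
#' @param min_depth minimum read depth for a base to count as covered.
#' @return covered genome size in Mbp.
#' @export
genome_coverage_mbp <- function(depth_track, min_depth = 6L) {
  dt <- data.table::as.data.table(depth_track)
  if (nrow(dt) == 0L) return(0)
  .assert(all(c("chrom", "start", "end", "depth") %in% names(dt)),
          "depth track needs columns chrom, start, end, depth")
  .assert(all(dt$depth >= 0), "negative depth in coverage track")
  .assert(all(dt$end >= dt$start), "intervals must satisfy end >= start")
  covered <- dt[depth >= min_depth]
  if (nrow(covered) == 0L) return(0)
  sum(covered$end - covered$start + 1) / 1e6
}

#' Coverage-adjusted tumor mutational burden
#'
#' Divides the number of consensus somatic variants by the Mbp of genome
#' covered by sequencing, giving mutations/Mbp.
#'
#' @param consensus consensus variant set (data.frame) or an integer count.
#' @param mbp Mbp of genome covered (must be > 0).
#' @return a list of class `tmb_record` with `raw_count`, `mbp_covered` and
#'   `adjusted` (mutations/Mbp).
#' @export
coverage_adjusted_tmb <- function(consensus, mbp) {
  n <- if (is.data.frame(consensus)) nrow(consensus) else consensus
  .assert(.is_count(n), "`consensus` must be a variant table or a count")
  .assert(is.numeric(mbp) && length(mbp) == 1L && !is.na(mbp) && mbp >= 0,
          "`mbp` must be a single non-negative number")
  if (mbp == 0) {
    stop("TMB undefined: zero Mbp covered", call. = FALSE)
  }
  structure(list(raw_count = as.integer(n), mbp_covered = mbp,
                 adjusted = n / mbp),
            class = "tmb_record")
}

#' @export
print.tmb_record <- function(x, ...) {
  cat(sprintf("TMB: %d consensus variants / %.2f Mbp = %.2f mutations/Mbp\n",
              x$raw_count, x$mbp_covered, x$adjusted))
  invisible(x)
}

#' Per-patient cross-caller TMB variability
#'
#' The median of absolute pairwise differences in TMB between callers, divided
#' by the median TMB across callers. A value of 0 means all callers agree; a
#' value near 1 means typical caller disagreement is as large as the burden
#' itself.
#'
#' @param per_caller_tmb named numeric vector of per-caller TMB values
#'   (raw counts or coverage-adjusted; both supported).
#' @return a single non-negative number.
#' @export
caller_variability <- function(per_caller_tmb) {
  v <- unlist(per_caller_tmb)
  .assert(is.numeric(v) && length(v) >= 2L, "need TMB from at least 2 callers")
  med <- stats::median(v)
  if (med == 0) stop("caller variability undefined: median TMB is 0", call. = FALSE)
  pairs <- utils::combn(v, 2L)
  stats::median(abs(pairs[1L, ] - pairs[2L, ])) / med
}

#' Cohort-level caller variability
#'
#' Median across patients of the per-patient [caller_variability()] values.
#'
#' @param per_patient_variability numeric vector, one value per patient.
#' @return the cohort median.
#' @export
cohort_variability <- function(per_patient_variability) {
  .assert(is.numeric(per_patient_variability) && length(per_patient_variability) >= 1L,
          "need at least one patient")
  stats::median(per_patient_variability)
}

#' Range of per-caller variant counts as a fraction of the median
#'
#' The difference between the highest and lowest per-caller counts for one
#' patient, and that range as a fraction of the median per-caller count.
#'
#' @param per_caller_counts named numeric vector of per-caller variant counts.
#' @return list with `range` and `fraction_of_median`.
#' @export
tmb_range_fraction <- function(per_caller_counts) {
  v <- unlist(per_caller_counts)
  .assert(is.numeric(v) && length(v) >= 2L, "need counts from at least 2 callers")
  med <- stats::median(v)
  if (med == 0) stop("range fraction undefined: median count is 0", call. = FALSE)
  rg <- max(v) - min(v)
  list(range = rg, fraction_of_median = rg / med)
}
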