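## internal helpers shared across modules

.assert <- function(cond, msg) {
  if (!isTRUE(cond)) stop(msg, call. = FALSE)
}

.is_count <- function(x) is.numeric(x) && length(x) == 1L && !is.na(x) && x >= 0 && x == floor(x)

#' Derive a reproducible child seed from a root seed and a label
#'
#' A single root seed deterministically derives per-patient (or per-stage)
#' sub-seeds, so regenerating one patient does not depend on how many other
#' patients were drawn before it. The derivation is a small multiplicative
#' hash of the label folded into the root seed, kept strictly below 2^31.
#'
#' @param root integer root seed.
#' @param label character label (e.g. a patient id).
#' @return an integer seed in `[1, 2^31 - 2]`.
#' @export
derive_seed <- function(root, label) {
  .assert(.is_count(root), "`root` must be a non-negative integer seed")
  .assert(is.character(label) && length(label) == 1L, "`label` must be a single string")
  m <- 2147483647  # 2^31 - 1, Mersenne prime
  h <- root %% m
  for (ch in utf8ToInt(label)) {
    h <- (h * 131 + ch) %% m
  }
  as.integer(h %% (m - 1L) + 1L)
}

## run code under a locally-set RNG seed, restoring the caller's RNG state
.with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Median burden across multiple tumor samples of one patient
#'
#' Patients with multiple tumor samples contribute a single per-patient value:
#' the median across samples (midpoint of the two central order statistics for
#' an even number of samples).
#'
#' @param per_sample_values numeric vector, one value per tumor sample.
#' @return the median as a single number.
#' @export
aggregate_multisample <- function(per_sample_values) {
  .assert(is.numeric(per_sample_values) && length(per_sample_values) >= 1L,
          "`per_sample_values` must contain at least one sample value")
  .assert(!anyNA(per_sample_values), "`per_sample_values` must not contain NA")
  stats::median(per_sample_values)
}

## 0-based half-open BED interval -> 1-based closed coordinates
.bed0_to_1based <- function(start0, end0) {
  list(start = start0 + 1L, end = end0)
}

.pos1_to_bed0 <- function(start1, end1) {
  list(start = start1 - 1L, end = end1)
}

.amino_acids <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
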