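## Neoepitope window enumeration and closest-normal-peptide search.
##
## Candidate neoepitopes are all 8-24 aa windows of a mutated protein that
## contain at least one altered residue; a single interior substitution in a
## long protein therefore yields sum(8:24) = 272 windows. Window counts and
## distinct peptide sequences are both reported, since identical strings from
## different windows collapse for burden counting.

.windows_from_starts <- function(protein, starts, L) {
  if (length(starts) == 0L) return(NULL)
  data.table::data.table(
    sequence = substring(protein, starts, starts + L - 1L),
    length = L,
    start = starts
  )
}

.collapse_windows <- function(win_list) {
  dt <- data.table::rbindlist(win_list)
  if (is.null(dt) || nrow(dt) == 0L) {
    out <- data.table::data.table(sequence = character(), length = integer(),
                                  start = integer(), windows = integer())
    data.table::setattr(out, "n_windows", 0L)
    data.table::setattr(out, "n_distinct", 0L)
    return(out)
  }
  n_windows <- nrow(dt)
  out <- dt[, .(length = length[1L], start = start[1L], windows = .N),
            by = sequence]
  data.table::setattr(out, "n_windows", n_windows)
  data.table::setattr(out, "n_distinct", nrow(out))
  out[]
}

#' Enumerate candidate neoepitope windows around a substituted residue
#'
#' Returns every subsequence window of each length in `lengths` that covers
#' the altered position, truncated at the protein termini. Duplicate peptide
#' strings are collapsed (the `windows` column records multiplicity); the
#' total window count and distinct-sequence count are attached as attributes
#' `n_windows` and `n_distinct`.
#'
#' @param protein the post-substitution protein sequence (character string).
#' @param altered_position 1-based position of the substituted residue.
#' @param lengths integer vector of window lengths (default 8:24).
#' @return a data.table of distinct peptides (sequence, length, start, windows).
#' @export
enumerate_snv_peptides <- function(protein, altered_position, lengths = 8:24) {
  n <- nchar(protein)
  p <- altered_position
  .assert(.is_count(p) && p >= 1L && p <= n,
          "`altered_position` out of range for the protein")
  wins <- lapply(lengths, function(L) {
    if (L > n) return(NULL)
    lo <- max(1L, p - L + 1L)
    hi <- min(p, n - L + 1L)
    if (hi < lo) return(NULL)
    .windows_from_starts(protein, lo:hi, L)
  })
  .collapse_windows(wins)
}

#' Enumerate windows over a novel translated tail (frameshift semantics)
#'
#' For a frameshifted (or otherwise novel) C-terminal tail, enumerates every
#' window of each requested length that contains at least one novel residue,
#' drawing up to L-1 flanking residues from the unaltered upstream context.
#' Windows never extend past the end of the tail (translation stops there).
#'
#' @param novel_tail the post-frameshift translated sequence up to the first
#'   stop (may be empty, yielding an empty set).
#' @param upstream_context unaltered protein sequence immediately upstream.
#' @param lengths integer vector of window lengths (default 8:24).
#' @return a data.table as in [enumerate_snv_peptides()].
#' @export
enumerate_frameshift_peptides <- function(novel_tail, upstream_context,
                                          lengths = 8:24) {
  m <- nchar(novel_tail)
  if (m == 0L) return(.collapse_windows(list()))
  full <- paste0(upstream_context, novel_tail)
  u <- nchar(upstream_context)
  n <- nchar(full)
  wins <- lapply(lengths, function(L) {
    if (L > n) return(NULL)
    lo <- max(1L, u - L + 2L)           # window must reach residue u+1
    hi <- n - L + 1L                    # window must fit before the terminus
    if (hi < lo) return(NULL)
    .windows_from_starts(full, lo:hi, L)
  })
  .collapse_windows(wins)
}

#' Hamming mismatch count between two equal-length peptides
#'
#' @param a,b peptide strings of equal length.
#' @return number of positions at which the residues differ.
#' @export
mismatch_count <- function(a, b) {
  .assert(is.character(a) && is.character(b) && length(a) == 1L && length(b) == 1L,
          "`a` and `b` must be single peptide strings")
  .assert(nchar(a) == nchar(b), "peptides must have equal length for mismatch counting")
  sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
}

.blosum62 <- local({
  env <- new.env()
  function() {
    if (is.null(env$m)) {
      e <- new.env()
      utils::data("BLOSUM62", package = "Biostrings", envir = e)
      env$m <- e$BLOSUM62
    }
    env$m
  }
})

.blosum_score <- function(a_chars, b_chars, m) {
  sum(m[cbind(a_chars, b_chars)])
}

#' Closest normal peptide in a reference proteome
#'
#' Scans every same-length window of every proteome sequence and returns the
#' best match by maximal ungapped BLOSUM62 score. Ties are broken by the
#' higher weighted BLOSUM62 similarity (score against the candidate divided by
#' the candidate's self-score), remaining ties by lexicographic order of the
#' candidate peptide. The mismatch count against the winner is the Hamming
#' distance.
#'
#' This exhaustive scan is deterministic and exact; a database-search E-value
#' ranking would agree in rank for ungapped same-length matches but depends on
#' search heuristics and database size.
#'
#' @param neo neoepitope peptide string.
#' @param proteome character vector (or `Biostrings::AAStringSet`) of normal
#'   protein sequences.
#' @param matrix substitution matrix (default: BLOSUM62 from Biostrings).
#' @return list with `peptide` (best normal window), `mismatches`, `score`
#'   and `weighted_similarity`.
#' @export
closest_normal_peptide <- function(neo, proteome, matrix = NULL) {
  if (methods::is(proteome, "XStringSet")) proteome <- as.character(proteome)
  .assert(is.character(proteome) && length(proteome) >= 1L,
          "proteome must be a non-empty set of protein sequences")
  m <- if (is.null(matrix)) .blosum62() else matrix
  L <- nchar(neo)
  neo_chars <- strsplit(neo, "")[[1]]
  best <- NULL
  for (seqs in proteome) {
    n <- nchar(seqs)
    if (n < L) next
    chars <- strsplit(seqs, "")[[1]]
    n_win <- n - L + 1L
    # score(start) = sum_j M[neo_j, chars[start + j - 1]]
    scores <- numeric(n_win)
    for (j in seq_len(L)) {
      scores <- scores + unname(m[neo_chars[j], chars[j:(j + n_win - 1L)]])
    }
    top <- which(scores == max(scores))
    for (s in top) {
      cand_chars <- chars[s:(s + L - 1L)]
      cand <- paste(cand_chars, collapse = "")
      sc <- scores[s]
      self <- .blosum_score(cand_chars, cand_chars, m)
      ws <- if (self > 0) sc / self else -Inf
      better <- is.null(best) ||
        sc > best$score ||
        (sc == best$score && ws > best$weighted_similarity) ||
        (sc == best$score && ws == best$weighted_similarity && cand < best$peptide)
      if (better) {
        best <- list(peptide = cand,
                     mismatches = sum(cand_chars != neo_chars),
                     score = sc, weighted_similarity = ws)
      }
    }
  }
  .assert(!is.null(best), "proteome contains no sequence of sufficient length")
  best
}
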