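## Variant representation, normalization and file IO.
##
## A variant call set is a data.table with columns chrom, pos (1-based, VCF
## convention), ref, alt and vclass in {SNV, insertion, deletion}. Identity
## for all set operations is the normalized (chrom, pos, ref, alt) key.

.classify_variant <- function(ref, alt) {
  data.table::fifelse(nchar(ref) == nchar(alt), "SNV",
                      data.table::fifelse(nchar(ref) < nchar(alt), "insertion", "deletion"))
}

#' Normalize variants to left-aligned, minimal representation
#'
#' Trims shared suffix bases, then shared prefix bases (advancing `pos`), so
#' that equivalent calls from different callers share one identity key.
#' Multi-caller set operations are only meaningful after this normalization.
#'
#' @param variants data.frame with columns `chrom`, `pos`, `ref`, `alt`.
#' @return a data.table with normalized `pos`, `ref`, `alt` and a recomputed
#'   `vclass` column.
#' @export
normalize_variants <- function(variants) {
  .assert(all(c("chrom", "pos", "ref", "alt") %in% names(variants)),
          "variants must have columns chrom, pos, ref, alt")
  dt <- data.table::as.data.table(variants)
  .assert(nrow(dt) == 0L || all(dt$pos >= 1L), "variant pos must be >= 1")
  .assert(nrow(dt) == 0L || all(dt$ref != dt$alt), "ref must differ from alt")
  if (nrow(dt) == 0L) {
    dt[, vclass := character(0)]
    return(dt[])
  }
  norm1 <- function(pos, ref, alt) {
    r <- strsplit(ref, "")[[1]]
    a <- strsplit(alt, "")[[1]]
    # trim common suffix
    while (length(r) > 1L && length(a) > 1L && r[length(r)] == a[length(a)]) {
      r <- r[-length(r)]
      a <- a[-length(a)]
    }
    # trim common prefix, advancing pos
    while (length(r) > 1L && length(a) > 1L && r[1L] == a[1L]) {
      r <- r[-1L]
      a <- a[-1L]
      pos <- pos + 1L
    }
    list(pos = pos, ref = paste(r, collapse = ""), alt = paste(a, collapse = ""))
  }
  out <- mapply(norm1, dt$pos, dt$ref, dt$alt, SIMPLIFY = FALSE)
  dt[, pos := vapply(out, `[[`, numeric(1), "pos")]
  dt[, ref := vapply(out, `[[`, character(1), "ref")]
  dt[, alt := vapply(out, `[[`, character(1), "alt")]
  dt[, vclass := .classify_variant(ref, alt)]
  dt[]
}

.variant_key <- function(dt) {
  paste(dt$chrom, dt$pos, dt$ref, dt$alt, sep = ":")
}

#' Read somatic variant calls from a VCF file
#'
#' Parses a VCF 4.x file, splits multi-allelic records into one call per ALT
#' allele, and normalizes each call to left-aligned minimal representation.
#'
#' @param path path to an uncompressed or gzipped VCF file.
#' @return a data.table of normalized calls (chrom, pos, ref, alt, vclass).
#' @export
read_vcf_calls <- function(path) {
  .assert(file.exists(path), paste0("VCF file not found: ", path))
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fx <- vcfR::getFIX(v)
  if (is.null(dim(fx))) fx <- matrix(fx, nrow = 1, dimnames = list(NULL, names(fx)))
  if (nrow(fx) == 0L) {
    return(data.table::data.table(chrom = character(), pos = integer(),
                                  ref = character(), alt = character(),
                                  vclass = character()))
  }
  alt_split <- strsplit(fx[, "ALT"], ",", fixed = TRUE)
  n_alt <- lengths(alt_split)
  bad <- which(is.na(fx[, "POS"]) | is.na(fx[, "REF"]) | n_alt == 0L)
  if (length(bad)) {
    stop(sprintf("malformed VCF record at data line %d in %s", bad[1L], path),
         call. = FALSE)
  }
  dt <- data.table::data.table(
    chrom = rep(fx[, "CHROM"], n_alt),
    pos   = rep(as.integer(fx[, "POS"]), n_alt),
    ref   = rep(fx[, "REF"], n_alt),
    alt   = unlist(alt_split)
  )
  dt <- dt[alt != "*"]
  normalize_variants(dt)
}

#' Write variant calls to a minimal VCF 4.2 file
#'
#' @param variants data.frame with columns chrom, pos, ref, alt.
#' @param path output path (plain text).
#' @return the path, invisibly.
#' @export
write_vcf_calls <- function(variants, path) {
  dt <- data.table::as.data.table(variants)
  data.table::setorder(dt, chrom, pos, ref, alt)
  hdr <- c("##fileformat=VCFv4.2",
           "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
  body <- if (nrow(dt)) {
    sprintf("%s\t%d\t.\t%s\t%s\t.\tPASS\t.", dt$chrom, as.integer(dt$pos), dt$ref, dt$alt)
  } else character(0)
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read a per-base depth track from a BED-like file
#'
#' The file uses BED conventions (0-based, half-open intervals) with a fourth
#' column giving read depth; coordinates are converted to 1-based closed
#' intervals internally.
#'
#' @param path path to a BED file with columns chrom, start, end, depth.
#' @return a data.table with columns chrom, start, end (1-based closed), depth.
#' @export
read_coverage_bed <- function(path) {
  .assert(file.exists(path), paste0("coverage BED not found: ", path))
  dt <- data.table::fread(path, header = FALSE, sep = "\t",
                          col.names = c("chrom", "start", "end", "depth"))
  conv <- .bed0_to_1based(dt$start, dt$end)
  dt[, `:=`(start = conv$start, end = conv$end)]
  .assert(all(dt$depth >= 0), "negative depth in coverage track")
  dt[]
}

#' Write a depth track as a BED file (0-based half-open)
#'
#' @param track data.table with 1-based closed columns chrom, start, end, depth.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_coverage_bed <- function(track, path) {
  dt <- data.table::as.data.table(track)
  conv <- .pos1_to_bed0(dt$start, dt$end)
  out <- data.table::data.table(dt$chrom, conv$start, conv$end, dt$depth)
  data.table::fwrite(out, path, sep = "\t", col.names = FALSE)
  invisible(path)
}
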