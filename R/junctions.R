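## Tumor-specific splice junction filtering against a normal compendium.
##
## Junction coordinates follow the STAR SJ.out.tab dialect: 1-based positions
## of the first (donor) and last (acceptor) intronic base. Getting this
## convention wrong by one base silently empties the filter, so all readers
## convert explicitly.

.sj_motifs <- c("other", "GT-AG", "GT-AG", "GC-AG", "GC-AG", "AT-AC", "AT-AC")
.sj_strands <- c(".", "+", "-")

#' Read a STAR SJ.out.tab junction table
#'
#' Columns: chrom, intron start (1-based first intronic base), intron end
#' (last intronic base), strand code (0 undefined / 1 + / 2 -), motif code
#' (0 non-canonical, 1-2 GT-AG, 3-4 GC-AG, 5-6 AT-AC), annotated flag,
#' unique-mapping reads, multi-mapping reads, max overhang.
#'
#' @param path path to an SJ.out.tab file.
#' @return a data.table of junction records (chrom, donor, acceptor, strand,
#'   motif, reads, fully_annotated; annotation-end flags added by
#'   [annotate_junctions()]).
#' @export
read_star_sj <- function(path) {
  .assert(file.exists(path), paste0("SJ table not found: ", path))
  dt <- data.table::fread(path, header = FALSE, sep = "\t")
  .assert(ncol(dt) >= 7L, paste0("malformed SJ.out.tab (needs >= 7 columns): ", path))
  data.table::setnames(dt, 1:7, c("chrom", "donor", "acceptor", "strand_code",
                                  "motif_code", "annotated", "reads"))
  bad <- which(dt$donor >= dt$acceptor | dt$reads < 0 |
                 !(dt$strand_code %in% 0:2) | !(dt$motif_code %in% 0:6))
  if (length(bad)) {
    stop(sprintf("malformed junction row at line %d in %s", bad[1L], path),
         call. = FALSE)
  }
  data.table::data.table(
    chrom = as.character(dt$chrom),
    donor = as.integer(dt$donor),
    acceptor = as.integer(dt$acceptor),
    strand = .sj_strands[dt$strand_code + 1L],
    motif = .sj_motifs[dt$motif_code + 1L],
    reads = as.integer(dt$reads),
    fully_annotated = dt$annotated == 1L
  )
}

#' Write junction records as a STAR SJ.out.tab table
#'
#' @param junctions data.frame of junction records (see [read_star_sj()]).
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_star_sj <- function(junctions, path) {
  dt <- data.table::as.data.table(junctions)
  strand_code <- match(dt$strand, .sj_strands) - 1L
  motif_code <- c("other" = 0L, "GT-AG" = 1L, "GC-AG" = 3L, "AT-AC" = 5L)[dt$motif]
  out <- data.table::data.table(dt$chrom, dt$donor, dt$acceptor, strand_code,
                                motif_code,
                                as.integer(dt$fully_annotated),
                                dt$reads, 0L, 30L)
  data.table::fwrite(out, path, sep = "\t", col.names = FALSE)
  invisible(path)
}

.jx_key <- function(dt, with_strand = TRUE) {
  if (with_strand) paste(dt$chrom, dt$donor, dt$acceptor, dt$strand, sep = ":")
  else paste(dt$chrom, dt$donor, dt$acceptor, sep = ":")
}

#' Build a normal-junction compendium
#'
#' Unions the identity keys (chrom, donor, acceptor, strand) of all junctions
#' seen in any normal sample. A single supporting read in a single normal
#' sample is enough for inclusion: any appearance in normal tissue later
#' eliminates the junction from a tumor set.
#'
#' @param normal_junction_tables list of junction data.frames (as returned by
#'   [read_star_sj()]).
#' @return an object of class `junction_compendium`.
#' @export
build_compendium <- function(normal_junction_tables) {
  if (length(normal_junction_tables) == 0L) {
    dt <- data.table::data.table(chrom = character(), donor = integer(),
                                 acceptor = integer(), strand = character())
  } else {
    dt <- data.table::rbindlist(lapply(normal_junction_tables, function(tb) {
      tb <- data.table::as.data.table(tb)
      .assert(all(c("chrom", "donor", "acceptor") %in% names(tb)),
              "normal junction tables need columns chrom, donor, acceptor")
      bad <- which(tb$donor >= tb$acceptor)
      if (length(bad)) {
        stop(sprintf("malformed junction row %d: donor must precede acceptor", bad[1L]),
             call. = FALSE)
      }
      if (!"strand" %in% names(tb)) tb$strand <- "."
      tb[, .(chrom = as.character(chrom), donor, acceptor, strand)]
    }))
    dt <- unique(dt, by = c("chrom", "donor", "acceptor", "strand"))
  }
  structure(list(
    junctions = dt,
    exact = unique(.jx_key(dt, TRUE)),
    nostrand = unique(.jx_key(dt, FALSE))
  ), class = "junction_compendium")
}

#' @export
print.junction_compendium <- function(x, ...) {
  cat(sprintf("Normal junction compendium: %d unique junctions\n",
              length(x$nostrand)))
  invisible(x)
}

#' Membership query against a junction compendium
#'
#' Strand participates in identity only when both records have a known
#' strand; an unknown strand (".") matches either orientation.
#'
#' @param junctions data.frame of junction records.
#' @param compendium a `junction_compendium`.
#' @return logical vector, one entry per junction.
#' @export
in_compendium <- function(junctions, compendium) {
  dt <- data.table::as.data.table(junctions)
  if (nrow(dt) == 0L) return(logical(0))
  if (!"strand" %in% names(dt)) dt$strand <- "."
  known <- dt$strand %in% c("+", "-")
  hit <- logical(nrow(dt))
  # known-strand query: same strand, or a strand-unknown compendium entry
  hit[known] <- .jx_key(dt[known], TRUE) %in% compendium$exact |
    paste(dt$chrom[known], dt$donor[known], dt$acceptor[known], ".", sep = ":") %in%
      compendium$exact
  # unknown-strand query: any orientation matches
  hit[!known] <- .jx_key(dt[!known], FALSE) %in% compendium$nostrand
  hit
}

#' Filter a patient's junctions down to putative tumor-specific junctions
#'
#' Applies, in order: (1) keep only canonical splice motifs (GT-AG, GC-AG,
#' AT-AC); (2) remove junctions present in the normal compendium; (3) remove
#' fully annotated junctions (the exact donor-acceptor pair occurs in an
#' annotated transcript); (4) remove junctions where neither end is
#' annotated. No minimum read support is imposed on the tumor junctions.
#' Input order is preserved and duplicate identity keys collapse to one.
#'
#' @param patient_junctions data.frame of junction records with logical
#'   columns left_annotated, right_annotated, fully_annotated.
#' @param compendium a `junction_compendium` of normal junctions.
#' @return the retained junctions, with an attribute `removed` giving per-rule
#'   removal counts.
#' @export
tumor_specific_junctions <- function(patient_junctions, compendium) {
  dt <- data.table::as.data.table(patient_junctions)
  need <- c("chrom", "donor", "acceptor", "motif",
            "left_annotated", "right_annotated", "fully_annotated")
  .assert(all(need %in% names(dt)),
          paste0("patient junctions need columns: ", paste(need, collapse = ", ")))
  if (!"strand" %in% names(dt)) dt$strand <- "."
  dt <- unique(dt, by = c("chrom", "donor", "acceptor", "strand"))
  removed <- c(non_canonical = 0L, in_compendium = 0L,
               fully_annotated = 0L, unannotated_both_ends = 0L)
  keep <- dt$motif %in% c("GT-AG", "GC-AG", "AT-AC")
  removed["non_canonical"] <- sum(!keep)
  dt <- dt[keep]
  if (nrow(dt)) {
    hit <- in_compendium(dt, compendium)
    removed["in_compendium"] <- sum(hit)
    dt <- dt[!hit]
  }
  if (nrow(dt)) {
    removed["fully_annotated"] <- sum(dt$fully_annotated)
    dt <- dt[!(fully_annotated)]
  }
  if (nrow(dt)) {
    neither <- !dt$left_annotated & !dt$right_annotated
    removed["unannotated_both_ends"] <- sum(neither)
    dt <- dt[!neither]
  }
  data.table::setattr(dt, "removed", removed)
  dt[]
}

#' Tumor-specific junction burden
#'
#' @param tumor_specific output of [tumor_specific_junctions()].
#' @return number of distinct retained junctions.
#' @export
junction_burden <- function(tumor_specific) {
  dt <- data.table::as.data.table(tumor_specific)
  if (nrow(dt) == 0L) return(0L)
  if (!"strand" %in% names(dt)) dt$strand <- "."
  nrow(unique(dt, by = c("chrom", "donor", "acceptor", "strand")))
}

#' Splice-site annotation sets from transcript models
#'
#' Derives annotated donor sites, acceptor sites, and full donor-acceptor
#' pairs from a GTF (GENCODE dialect) or from an already-imported exon table.
#' Intron coordinates are the first and last intronic base between
#' consecutive exons of each transcript, matching the SJ.out.tab dialect.
#'
#' @param gtf path to a GTF file (read with rtracklayer) or a data.frame of
#'   exons with columns chrom, start, end, strand, transcript_id.
#' @return list with character sets `left_sites`, `right_sites` (chrom:pos)
#'   and `pairs` (chrom:donor:acceptor).
#' @export
splice_annotation <- function(gtf) {
  if (is.character(gtf)) {
    .assert(requireNamespace("rtracklayer", quietly = TRUE),
            "reading GTF files requires the rtracklayer package")
    gr <- as.data.frame(rtracklayer::import(gtf))
    gr <- gr[gr$type == "exon", ]
    exons <- data.table::data.table(
      chrom = as.character(gr$seqnames),
      start = gr$start,
      end = gr$end,
      strand = as.character(gr$strand),
      transcript_id = gr$transcript_id
    )
  } else {
    exons <- data.table::as.data.table(gtf)
  }
  .assert(all(c("chrom", "start", "end", "transcript_id") %in% names(exons)),
          "exon table needs columns chrom, start, end, transcript_id")
  data.table::setorder(exons, transcript_id, start)
  introns <- exons[, {
    if (.N < 2L) NULL
    else .(chrom = chrom[-.N], donor = end[-.N] + 1L, acceptor = start[-1L] - 1L)
  }, by = transcript_id]
  introns <- introns[acceptor >= donor]
  list(
    left_sites = unique(paste(introns$chrom, introns$donor, sep = ":")),
    right_sites = unique(paste(introns$chrom, introns$acceptor, sep = ":")),
    pairs = unique(paste(introns$chrom, introns$donor, introns$acceptor, sep = ":"))
  )
}

#' Populate annotation flags on junction records
#'
#' @param junctions data.frame of junction records.
#' @param annotation output of [splice_annotation()].
#' @return the junctions with left_annotated, right_annotated and
#'   fully_annotated set.
#' @export
annotate_junctions <- function(junctions, annotation) {
  dt <- data.table::as.data.table(junctions)
  dt[, left_annotated := paste(chrom, donor, sep = ":") %in% annotation$left_sites]
  dt[, right_annotated := paste(chrom, acceptor, sep = ":") %in% annotation$right_sites]
  dt[, fully_annotated := paste(chrom, donor, acceptor, sep = ":") %in% annotation$pairs]
  dt[]
}
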