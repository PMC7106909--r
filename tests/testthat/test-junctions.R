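# junction fixture helpers
jx_row <- function(donor, acceptor = donor + 500, motif = "GT-AG",
                   strand = "+", left = TRUE, right = FALSE, full = FALSE,
                   reads = 5, chrom = "chr1") {
  data.frame(chrom = chrom, donor = donor, acceptor = acceptor,
             strand = strand, motif = motif, reads = reads,
             left_annotated = left, right_annotated = right,
             fully_annotated = full)
}

test_that("compendium is the union of normal junction keys, single read suffices", {
  t1 <- data.frame(chrom = "chr1", donor = c(100, 200), acceptor = c(600, 700),
                   strand = "+", reads = c(1, 10))
  t2 <- data.frame(chrom = "chr1", donor = c(200, 300), acceptor = c(700, 800),
                   strand = "+", reads = 4)
  comp <- build_compendium(list(t1, t2))
  expect_length(comp$nostrand, 3)  # union, shared junction counted once
  # single-read normal junction is a full member
  expect_true(in_compendium(jx_row(100, 600), comp))
  expect_length(build_compendium(list())$nostrand, 0)
  bad <- data.frame(chrom = "chr1", donor = 500, acceptor = 400, strand = "+")
  expect_error(build_compendium(list(bad)), "donor must precede")
})

test_that("each of the four removal rules acts independently (12-junction fixture)", {
  comp <- build_compendium(list(
    data.frame(chrom = "chr1", donor = c(1000, 2000), acceptor = c(1500, 2600),
               strand = "+")))
  fixture <- rbind(
    jx_row(5000),                            # 1 retained: canonical, novel, left-annotated
    jx_row(5100, left = FALSE, right = TRUE),# 2 retained: right-annotated only
    jx_row(5200, motif = "GC-AG"),           # 3 retained: alternative canonical motif
    jx_row(5300, motif = "AT-AC"),           # 4 retained
    jx_row(5400, motif = "other"),           # 5 removed: non-canonical
    jx_row(1000, 1500),                      # 6 removed: in compendium
    jx_row(2000, 2600),                      # 7 removed: in compendium
    jx_row(5500, left = TRUE, right = TRUE, full = TRUE),  # 8 removed: fully annotated
    jx_row(5600, left = FALSE, right = FALSE),             # 9 removed: neither end
    jx_row(5700, motif = "other", left = FALSE, right = FALSE), # 10 removed (two rules)
    jx_row(5800, reads = 1),                 # 11 retained: no minimum tumor read support
    jx_row(1000, 1500, strand = "-")         # 12 retained: other strand, not the compendium key
  )
  out <- tumor_specific_junctions(fixture, comp)
  expect_setequal(out$donor, c(5000, 5100, 5200, 5300, 5800, 1000))
  expect_equal(sum(out$donor == 1000 & out$strand == "-"), 1)
  rem <- attr(out, "removed")
  expect_equal(unname(rem["non_canonical"]), 2)
  expect_equal(unname(rem["in_compendium"]), 2)
  expect_equal(unname(rem["fully_annotated"]), 1)
  expect_equal(unname(rem["unannotated_both_ends"]), 1)
  # every retained junction satisfies the conjunction of the four rules
  expect_true(all(out$motif %in% c("GT-AG", "GC-AG", "AT-AC")))
  expect_true(all(!in_compendium(out, comp)))
  expect_true(all(!out$fully_annotated))
  expect_true(all(out$left_annotated | out$right_annotated))
})

test_that("unknown strand matches either orientation in the compendium", {
  comp <- build_compendium(list(
    data.frame(chrom = "chr1", donor = 100, acceptor = 600, strand = "+"),
    data.frame(chrom = "chr1", donor = 200, acceptor = 700, strand = ".")))
  expect_true(in_compendium(jx_row(100, 600, strand = "+"), comp))
  expect_false(in_compendium(jx_row(100, 600, strand = "-"), comp))
  expect_true(in_compendium(jx_row(100, 600, strand = "."), comp))
  # strand-unknown compendium entry matches any query strand
  expect_true(in_compendium(jx_row(200, 700, strand = "-"), comp))
})

test_that("the filter is a pure, idempotent set operation", {
  comp_small <- build_compendium(list(
    data.frame(chrom = "chr1", donor = 1000, acceptor = 1500, strand = "+")))
  comp_big <- build_compendium(list(
    data.frame(chrom = "chr1", donor = c(1000, 5000), acceptor = c(1500, 5500),
               strand = "+")))
  set.seed(5)
  fixture <- do.call(rbind, lapply(seq(3000, 6000, by = 150), function(d)
    jx_row(d, d + 500, motif = sample(c("GT-AG", "other"), 1),
           left = sample(c(TRUE, FALSE), 1), right = sample(c(TRUE, FALSE), 1))))
  out1 <- tumor_specific_junctions(fixture, comp_small)
  # idempotence and containment
  out2 <- tumor_specific_junctions(out1, comp_small)
  expect_equal(out2$donor, out1$donor)
  expect_true(all(out1$donor %in% fixture$donor))
  # growing the compendium can only shrink the output
  out_big <- tumor_specific_junctions(fixture, comp_big)
  expect_lte(nrow(out_big), nrow(out1))
  # complete subtraction: patient junctions all in compendium
  incomp <- jx_row(1000, 1500)
  expect_equal(nrow(tumor_specific_junctions(incomp, comp_small)), 0)
})

test_that("junction burden counts distinct identity keys", {
  expect_equal(junction_burden(jx_row(100)[0, ]), 0)
  dup <- rbind(jx_row(100), jx_row(100), jx_row(200))
  expect_equal(junction_burden(dup), 2)
})

test_that("planted tumor-specific junctions are recovered exactly from the generator", {
  co <- generate_cohort(tiny_cohort_config(seed = 21L))
  comp <- build_compendium(list(co$normal_junctions))
  rna_pats <- co$patients$patient[co$patients$has_rna]
  expect_gt(length(rna_pats), 0)
  for (pid in rna_pats) {
    jx <- co$junctions[co$junctions$patient == pid, ]
    if (nrow(jx) == 0) next
    out <- tumor_specific_junctions(jx, comp)
    truth_keys <- co$truth[[pid]]$true_junction_keys
    got_keys <- paste(out$chrom, out$donor, out$acceptor, out$strand, sep = ":")
    expect_setequal(got_keys, truth_keys)
    # planted novel junctions never collide with the compendium
    expect_false(any(truth_keys %in% comp$exact))
  }
})

test_that("SJ.out.tab round trip preserves coordinates, motif and strand", {
  jx <- rbind(jx_row(100, 700, motif = "GT-AG", strand = "+"),
              jx_row(900, 1400, motif = "AT-AC", strand = "-", full = TRUE),
              jx_row(2000, 2800, motif = "other", strand = "."))
  f <- tempfile(fileext = ".tab")
  write_star_sj(jx, f)
  back <- read_star_sj(f)
  expect_equal(back$donor, jx$donor)
  expect_equal(back$acceptor, jx$acceptor)
  expect_equal(back$motif, jx$motif)
  expect_equal(back$strand, jx$strand)
  expect_equal(back$fully_annotated, jx$fully_annotated)
  # malformed row (donor after acceptor) is rejected with its line number
  writeLines("chr1\t500\t400\t1\t1\t0\t3\t0\t20", f)
  expect_error(read_star_sj(f), "line 1")
})

test_that("annotation flags derive from transcript exon models", {
  # transcript with exons 1-100, 201-300, 401-500: introns 101-200, 301-400
  exons <- data.frame(chrom = "chr1", start = c(1, 201, 401),
                      end = c(100, 300, 500), strand = "+",
                      transcript_id = "TXA")
  ann <- splice_annotation(exons)
  expect_setequal(ann$pairs, c("chr1:101:200", "chr1:301:400"))
  jx <- rbind(jx_row(101, 200), jx_row(101, 250), jx_row(900, 950))
  flagged <- annotate_junctions(jx[, c("chrom", "donor", "acceptor", "strand",
                                       "motif", "reads")], ann)
  expect_equal(flagged$fully_annotated, c(TRUE, FALSE, FALSE))
  expect_equal(flagged$left_annotated, c(TRUE, TRUE, FALSE))
  expect_equal(flagged$right_annotated, c(TRUE, FALSE, FALSE))
})
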