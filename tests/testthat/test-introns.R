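test_that("transcript filters apply TPM, count and retention-fraction rules", {
  q <- function(tx, tpm, uc, rf) {
    data.frame(transcript = tx, sample_id = paste0("s", seq_along(tpm)),
               tpm = tpm, unique_counts = uc, retention_frac = rf)
  }
  # TPM in 2/4 samples >= 1 -> 50% >= 25%: passes
  quants <- rbind(
    q("TXPASS", c(1, 1, 0.5, 0.2), c(9, 9, 9, 9), c(0.2, 0.3, 0.1, 0.2)),
    q("TXLOWTPM", c(0.5, 0.4, 0.3, 0.2), c(9, 9, 9, 9), c(0.2, 0.3, 0.1, 0.2)),
    q("TXLOWCNT", c(2, 2, 2, 2), c(1, 2, 3, 4), c(0.2, 0.3, 0.1, 0.2)),
    q("TXNORET", c(2, 2, 2, 2), c(9, 9, 9, 9), c(0, 0, 0, 0)),
    q("TXALLRET", c(2, 2, 2, 2), c(9, 9, 9, 9), c(1, 1, 1, 1)))
  kept <- filter_transcripts(quants)
  expect_equal(kept, "TXPASS")
  expect_error(filter_transcripts(quants[0, ]), "empty")
})

test_that("MAD outlier rule matches hand-worked fixtures", {
  # median 10, unscaled MAD 0 -> threshold 10; 100 > 10 and >= 20
  expect_equal(intron_outlier_filter(c(10, 10, 10, 10, 100), 20), 5L)
  # all equal: nothing strictly exceeds the median
  expect_length(intron_outlier_filter(c(7, 7, 7, 7), 1), 0)
  # two introns: median 27.5, MAD 22.5, threshold 95; 50 fails
  expect_length(intron_outlier_filter(c(5, 50), 60), 0)
  # transcript-count condition is >=: count equal to transcript count passes
  expect_equal(intron_outlier_filter(c(10, 10, 10, 10, 100), 100), 5L)
  expect_length(intron_outlier_filter(c(10, 10, 10, 10, 100), 101), 0)
  expect_error(intron_outlier_filter(numeric(0), 1), "at least one")
})

test_that("MAD rule is order-invariant and scale-equivariant", {
  set.seed(31)
  for (i in 1:20) {
    counts <- rpois(sample(4:12, 1), 8)
    counts[sample(length(counts), 1)] <- 120
    tc <- sample(10:60, 1)
    base <- sort(intron_outlier_filter(counts, tc))
    perm <- sample(length(counts))
    expect_equal(sort(perm[intron_outlier_filter(counts[perm], tc)]), base)
    expect_equal(sort(intron_outlier_filter(counts * 3.5, tc * 3.5)), base)
  }
})

test_that("planted outliers are recovered; unperturbed introns never are", {
  set.seed(32)
  for (i in 1:15) {
    counts <- rpois(10, 20) + 1
    med <- median(counts); madv <- mad(counts, constant = 1)
    if (madv == 0) next
    tc <- sample(5:30, 1)
    planted <- max(med + 10 * madv, tc)
    idx <- sample(10, 1)
    counts[idx] <- planted
    got <- intron_outlier_filter(counts, tc)
    expect_true(idx %in% got)
    # only introns above the rule's threshold are reported
    thr <- median(counts) + 3 * mad(counts, constant = 1)
    expect_true(all(counts[got] > thr & counts[got] >= tc))
  }
})

test_that("normal-tissue RIs are removed by exact set difference", {
  expect_length(subtract_normal_ris(c("TX1:1", "TX2:2"), c("TX1:1", "TX2:2", "TX3:1")), 0)
  expect_equal(subtract_normal_ris(c("TX1:1", "TX2:2"), c("TX9:1")),
               c("TX1:1", "TX2:2"))
  expect_equal(subtract_normal_ris(c("TX1:1", "TX2:2", "TX3:3"), c("TX2:2")),
               c("TX1:1", "TX3:3"))
  # data.frame interface keyed by (transcript, intron_index)
  tum <- data.frame(transcript = c("TX1", "TX2"), intron_index = c(1, 2))
  nor <- data.frame(transcript = "TX2", intron_index = 2)
  expect_equal(subtract_normal_ris(tum, nor)$transcript, "TX1")
})

test_that("retained-intron peptides translate in the upstream frame", {
  # hand-built fixture: upstream MKT (9 nt, frame 0), intron starts with an
  # immediate in-frame stop -> no novel residues
  up <- "ATGAAAACC"          # M K T
  stopintron <- "TAAGGGGGG"
  expect_equal(nrow(ri_peptides(up, stopintron)), 0)

  # intron encoding exactly 10 novel residues before a stop; 8-mers only:
  # brute-force oracle over the translated peptide
  intron10 <- paste0(strrep("GGA", 10), "TAA")   # G x 10, then stop
  up_long <- strrep("ATGAAAACC", 4)              # 12 upstream residues
  res <- ri_peptides(up_long, intron10, lengths = 8)
  translated <- paste0(strrep("MKT", 4), strrep("G", 10))
  orc <- oracle_windows(translated, 13:22, 8)
  expect_equal(attr(res, "n_windows"), orc$n_windows)
  expect_equal(attr(res, "n_windows"), 10)
  expect_setequal(res$sequence, unique(orc$sequences))

  # hand translation of a 30-nt fixture; shifting the frame by one base
  # changes the translated tail
  up30 <- "ATGGATTCA"  # M D S
  intr <- "GCTGCAACTGCTGCAACTGCTGCAACTTAA"  # A A T A A T A A T *
  r_a <- ri_peptides(up30, intr, lengths = 8)
  expect_true(all(grepl("AAT", r_a$sequence)))
  r_b <- ri_peptides(paste0(up30, "G"), intr, lengths = 8)  # frame shifted
  expect_false(identical(sort(r_a$sequence), sort(r_b$sequence)))

  # ambiguous nucleotides stop translation with a warning
  expect_warning(ri_peptides(up, "GGANGGGGGGGGGGGGGGGGGGGGGGGGGG"),
                 "ambiguous")
})

test_that("detect_ris applies the expression and MAD filters jointly", {
  quants <- data.frame(
    transcript = rep(c("TXOK", "TXLOW"), each = 2),
    sample_id = rep(c("s1", "s2"), 2),
    tpm = c(5, 5, 0.1, 0.1), unique_counts = c(50, 50, 1, 1),
    retention_frac = c(0.3, 0.2, 0.3, 0.2))
  kept <- filter_transcripts(quants)
  counts <- data.frame(
    transcript = rep(c("TXOK", "TXLOW"), each = 4),
    intron_index = rep(1:4, 2),
    count = c(10, 10, 10, 200, 10, 10, 10, 200),
    transcript_count = 50)
  ris <- detect_ris(counts, kept)
  # the outlier on the unexpressed transcript is ignored
  expect_equal(ris, "TXOK:4")
})
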