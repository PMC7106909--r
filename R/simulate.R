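## Synthetic cohort generator.
##
## Every random draw happens under a sub-seed derived deterministically from
## the root seed and a stable label (patient id, stage name), so the bundle is
## bit-reproducible and stable under reordering of patient generation. Truth
## (true variants, true junctions, true RIs, response probabilities, hazard
## classes) is recorded before caller noise is applied.

.pick_rows <- function(dt, n) {
  dt[sample.int(nrow(dt), min(nrow(dt), n))]
}

.random_peptide <- function(n, len) {
  vapply(len, function(L) paste(sample(.amino_acids, L, replace = TRUE),
                                collapse = ""), character(1))
}

.random_bases <- function(n, len = 1L) {
  if (n == 0L) return(character(0))
  m <- matrix(sample(c("A", "C", "G", "T"), n * len, replace = TRUE), nrow = n)
  do.call(paste0, as.data.frame(m))
}

.hla_pools <- function() {
  list(
    classI = as.vector(outer(c("HLA-A*", "HLA-B*", "HLA-C*"),
                             sprintf("%02d:01", 1:10), paste0)),
    classII = as.vector(outer(c("HLA-DRB1*", "HLA-DQB1*", "HLA-DPB1*"),
                              sprintf("%02d:01", 1:10), paste0))
  )
}

## draw true variants on a 1-chromosome genome of `genome_bp` bases;
## returns a plain list of column vectors (hot path: kept data.table-free)
.draw_true_variants <- function(n_var, genome_bp, snv_fraction) {
  if (n_var == 0L) {
    return(list(chrom = character(), pos = integer(),
                ref = character(), alt = character(), vclass = character()))
  }
  # with-replacement draw + dedupe: collision probability is ~n^2 / genome_bp
  # (negligible at cohort scale) and it avoids the without-replacement setup
  # cost on a ~1e8-base genome
  pos <- unique(sort(sample.int(genome_bp, n_var, replace = TRUE)))
  n_var <- length(pos)
  cls <- sample(c("SNV", "insertion", "deletion"), n_var, replace = TRUE,
                prob = c(snv_fraction, (1 - snv_fraction) / 2,
                         (1 - snv_fraction) / 2))
  ref <- character(n_var); alt <- character(n_var)
  bases <- c("A", "C", "G", "T")
  is_snv <- cls == "SNV"
  n_snv <- sum(is_snv)
  ref[is_snv] <- sample(bases, n_snv, replace = TRUE)
  # shift the base index by 1-3 positions (mod 4): always a different base
  alt[is_snv] <- bases[(match(ref[is_snv], bases) - 1L +
                          sample.int(3L, n_snv, replace = TRUE)) %% 4L + 1L]
  is_ins <- cls == "insertion"
  if (any(is_ins)) {
    anchor <- sample(c("A", "C", "G", "T"), sum(is_ins), replace = TRUE)
    ref[is_ins] <- anchor
    alt[is_ins] <- paste0(anchor, .random_bases(sum(is_ins),
                                                len = sample(1:3, 1L)))
  }
  is_del <- cls == "deletion"
  if (any(is_del)) {
    anchor <- sample(c("A", "C", "G", "T"), sum(is_del), replace = TRUE)
    ref[is_del] <- paste0(anchor, .random_bases(sum(is_del),
                                                len = sample(1:3, 1L)))
    alt[is_del] <- anchor
  }
  list(chrom = rep("chr1", n_var), pos = pos, ref = ref, alt = alt,
       vclass = cls)
}

.subset_varlist <- function(v, idx) {
  lapply(v, `[`, idx)
}

.concat_varlist <- function(a, b) {
  Map(c, a, b)
}

## per-caller call set: sensitivity-thinned truth plus Poisson false positives
.draw_caller_calls <- function(truth, classes, sensitivity, fp_rate,
                               mbp, genome_bp, snv_fraction) {
  eligible <- .subset_varlist(truth, truth$vclass %in% classes)
  kept <- .subset_varlist(eligible,
                          stats::runif(length(eligible$pos)) <= sensitivity)
  n_fp <- stats::rpois(1L, fp_rate * mbp)
  calls <- kept
  if (n_fp > 0L) {
    fp <- .draw_true_variants(n_fp, genome_bp, snv_fraction)
    fp <- .subset_varlist(fp, fp$vclass %in% classes)
    calls <- .concat_varlist(kept, fp)
    dup <- duplicated(paste(calls$chrom, calls$pos, calls$ref, calls$alt))
    if (any(dup)) calls <- .subset_varlist(calls, !dup)
  }
  calls
}

#' Generate a complete synthetic immunotherapy cohort
#'
#' Produces every input the analysis pipeline consumes — per-caller somatic
#' call sets with coverage tracks, HLA genotypes and peptide-allele binding
#' affinities, tumor and normal junction tables, transcript and intron
#' quantifications, clinical outcomes — together with the generating truth.
#' Response labels are Bernoulli draws from the configured logistic model on
#' each patient's true log2 variant count; survival times are exponential
#' with the hazard scaled for patients whose true count strictly exceeds
#' their disease's 80th percentile.
#'
#' @param config a [cohort_config()].
#' @return a list of class `tvb_cohort`; see the package vignette for the
#'   component tables.
#' @export
generate_cohort <- function(config) {
  cfg <- validate_cohort_config(config)
  pools <- .hla_pools()
  ## shared assets: transcript pool, TCGA quantile table, junction universe
  shared <- .with_seed(derive_seed(cfg$seed, "shared"), {
    transcripts <- sprintf("TX%05d", seq_len(cfg$n_transcripts))
    n_introns <- sample(cfg$introns_per_transcript[["min"]]:cfg$introns_per_transcript[["max"]],
                        cfg$n_transcripts, replace = TRUE)
    tcga <- data.table::data.table(
      transcript = transcripts,
      q75_tpm = stats::rlnorm(cfg$n_transcripts, meanlog = 0.2, sdlog = 1.3))
    ## junction universe partitioned by donor position modulo 4:
    ##   0 -> normal compendium, 1 -> plantable tumor-specific (one end
    ##   annotated), 2 -> fully-annotated decoys, 3 -> unannotated decoys
    base <- sort(sample.int(2.4e7, cfg$compendium_size * 4L)) * 4L
    mk_jx <- function(offset) {
      donor <- base[seq_len(cfg$compendium_size)] + offset
      data.table::data.table(chrom = "chr1", donor = donor,
                             acceptor = donor + sample(80:5000, length(donor),
                                                       replace = TRUE),
                             strand = sample(c("+", "-"), length(donor),
                                             replace = TRUE))
    }
    list(transcripts = transcripts, n_introns = n_introns, tcga = tcga,
         compendium_jx = mk_jx(0L), novel_jx = mk_jx(1L),
         annotated_jx = mk_jx(2L), unannot_jx = mk_jx(3L))
  })

  types <- names(cfg$n_patients_per_type)
  patients <- list(); hla_rows <- list(); coverage_rows <- list()
  call_rows <- list(); truth_var_rows <- list(); peptide_rows <- list()
  binding_rows <- list(); jx_rows <- list(); truth <- list()
  sample_rows <- list()

  .caller_classes_split <- strsplit(cfg$caller_models$classes, ",", fixed = TRUE)
  for (ty in types) {
    n_ty <- cfg$n_patients_per_type[[ty]]
    if (n_ty == 0L) next
    ln <- cfg$tmb_lognormal[[ty]]
    mix <- cfg$therapy_mix[[ty]]
    if (is.null(mix)) mix <- c(aPD1 = 1)
    for (i in seq_len(n_ty)) {
      pid <- sprintf("%s_%03d", ty, i)
      rec <- .with_seed(derive_seed(cfg$seed, pid), {
        mbp_raw <- max(10, stats::rnorm(1L, cfg$coverage_mbp[["mean"]],
                                        cfg$coverage_mbp[["sd"]]))
        genome_bp <- round(mbp_raw * 1e6)
        mbp <- genome_bp / 1e6
        n_var <- max(0L, as.integer(round(stats::rlnorm(1L, ln[1], ln[2]))))
        truth_vars <- .draw_true_variants(n_var, genome_bp, cfg$snv_fraction)
        n_var <- length(truth_vars$pos)
        n_samples <- 1L + stats::rbinom(1L, 1L, cfg$multi_sample_fraction)
        samp_ids <- paste0(pid, "_S", seq_len(n_samples))
        calls <- list(); cov <- list()
        for (s in samp_ids) {
          for (ci in seq_len(nrow(cfg$caller_models))) {
            cc <- .draw_caller_calls(
              truth_vars, .caller_classes_split[[ci]],
              cfg$caller_models$sensitivity[ci], cfg$caller_models$fp_rate[ci],
              mbp, genome_bp, cfg$snv_fraction)
            n_cc <- length(cc$pos)
            if (n_cc) {
              cc$patient <- rep(pid, n_cc)
              cc$sample_id <- rep(s, n_cc)
              cc$caller <- rep(cfg$caller_models$caller[ci], n_cc)
              calls[[length(calls) + 1L]] <- cc
            }
          }
          cov[[length(cov) + 1L]] <- list(
            patient = c(pid, pid), sample_id = c(s, s),
            chrom = c("chr1", "chr1"),
            start = c(1L, genome_bp + 1L),
            end = c(genome_bp, genome_bp + 500000L),
            depth = c(10L, 5L))
        }
        ## HLA genotype: draws with replacement, duplicates = homozygosity
        a1 <- sample(pools$classI, cfg$n_hla_alleles[["classI"]], replace = TRUE)
        a2 <- sample(pools$classII, cfg$n_hla_alleles[["classII"]], replace = TRUE)
        allele_vec <- c(unique(a1), unique(a2))
        alleles <- list(
          patient = rep(pid, length(allele_vec)),
          allele = allele_vec,
          class = c(rep("I", length(unique(a1))), rep("II", length(unique(a2)))))
        ## thinned peptide-level simulation
        peptides <- binding <- NULL
        if (cfg$epitope_sample_rate > 0 && length(truth_vars$pos) > 0L) {
          picked <- which(stats::runif(length(truth_vars$pos)) <= cfg$epitope_sample_rate)
          if (length(picked)) {
            n_pep <- length(picked) * cfg$epitopes_per_variant
            lens <- sample(8:24, n_pep, replace = TRUE)
            pep <- .random_peptide(n_pep, lens)
            tx <- vapply(seq_len(n_pep), function(j)
              paste(sample(shared$transcripts,
                           sample(1:2, 1L)), collapse = ","), character(1))
            pv <- .subset_varlist(truth_vars, picked)
            peptides <- list(
              patient = rep(pid, n_pep), peptide = pep,
              source_variant = rep(paste(pv$chrom, pv$pos, pv$ref, pv$alt,
                                         sep = ":"),
                                   each = cfg$epitopes_per_variant),
              transcripts = tx,
              mismatches = 1L + stats::rpois(n_pep, 0.5))
            pa <- alleles$allele
            n_grid <- n_pep * length(pa)
            af <- cfg$affinity_model
            is_binder <- stats::runif(n_grid) <= af[["binder_fraction"]]
            affin <- 500 + stats::rlnorm(n_grid, af[["meanlog"]], af[["sdlog"]])
            affin[is_binder] <- exp(stats::runif(sum(is_binder), 0, log(500)))
            binding <- list(patient = rep(pid, n_grid),
                            peptide = rep(pep, each = length(pa)),
                            allele = rep(pa, times = n_pep),
                            affinity_nm = affin)
          }
        }
        ## RNA features
        has_rna <- ty %in% cfg$rna_types &&
          stats::runif(1L) <= cfg$rna_fraction
        jx <- NULL; true_jx_keys <- character(0)
        if (has_rna && !is.null(cfg$jx_lognormal[[ty]])) {
          jl <- cfg$jx_lognormal[[ty]]
          n_jx <- min(nrow(shared$novel_jx),
                      max(0L, as.integer(round(stats::rlnorm(1L, jl[1], jl[2])))))
          planted <- shared$novel_jx[sample.int(nrow(shared$novel_jx), n_jx)]
          planted[, `:=`(motif = sample(c("GT-AG", "GC-AG", "AT-AC"), .N,
                                        replace = TRUE, prob = c(0.9, 0.07, 0.03)),
                         reads = 1L + stats::rpois(.N, 3),
                         left_annotated = TRUE, right_annotated = FALSE,
                         fully_annotated = FALSE)]
          n_decoy <- as.integer(round(n_jx * 0.4))
          decoys <- list(
            .pick_rows(shared$compendium_jx, n_decoy)[,
              `:=`(motif = "GT-AG", reads = 1L + stats::rpois(.N, 5),
                   left_annotated = TRUE, right_annotated = TRUE,
                   fully_annotated = FALSE)],
            .pick_rows(shared$annotated_jx, n_decoy)[,
              `:=`(motif = "GT-AG", reads = 1L + stats::rpois(.N, 20),
                   left_annotated = TRUE, right_annotated = TRUE,
                   fully_annotated = TRUE)],
            .pick_rows(shared$unannot_jx, n_decoy)[,
              `:=`(motif = sample(c("GT-AG", "other"), .N, replace = TRUE),
                   reads = 1L + stats::rpois(.N, 2),
                   left_annotated = FALSE, right_annotated = FALSE,
                   fully_annotated = FALSE)])
          jx <- data.table::rbindlist(c(list(planted), decoys))
          jx[, patient := pid]
          true_jx_keys <- .jx_key(planted)
        }
        ## outcomes (survival drawn in the type-level second pass)
        therapy <- sample(names(mix), 1L, prob = as.numeric(mix))
        rm_rate <- cfg$response_missing_rate
        resp_missing <- stats::runif(1L) <= rm_rate
        rp <- cfg$response_model
        p_resp <- stats::plogis(rp[["beta0"]] +
                                  rp[["beta_log2"]] * log2(n_var + 1) +
                                  rp[["offset_aCTLA4"]] * (therapy == "aCTLA4"))
        response <- if (resp_missing) NA_integer_ else
          stats::rbinom(1L, 1L, p_resp)
        n_tv <- length(truth_vars$pos)
        list(
          patient = list(
            patient = pid, cancer_type = ty, therapy = therapy,
            response = response, has_rna = has_rna,
            n_unique_hla = length(unique(alleles$allele)),
            mbp_covered = mbp, true_n_variants = n_var,
            true_response_prob = p_resp),
          samples = list(patient = rep(pid, n_samples), sample_id = samp_ids),
          hla = alleles, coverage = cov,
          calls = calls,
          truth_vars = c(list(patient = rep(pid, n_tv)), truth_vars),
          peptides = peptides, binding = binding, jx = jx,
          truth = list(true_variant_keys = .variant_key(truth_vars),
                       true_junction_keys = true_jx_keys,
                       true_ri_keys = character(0),
                       response_prob = p_resp)
        )
      })
      patients[[pid]] <- rec$patient
      sample_rows[[pid]] <- rec$samples
      hla_rows[[pid]] <- rec$hla
      coverage_rows[[pid]] <- rec$coverage
      call_rows[[pid]] <- rec$calls
      truth_var_rows[[pid]] <- rec$truth_vars
      peptide_rows[[pid]] <- rec$peptides
      binding_rows[[pid]] <- rec$binding
      jx_rows[[pid]] <- rec$jx
      truth[[pid]] <- rec$truth
    }
  }
  patients <- data.table::rbindlist(patients)
  call_rows <- unlist(call_rows, recursive = FALSE, use.names = FALSE)
  coverage_rows <- unlist(coverage_rows, recursive = FALSE, use.names = FALSE)

  ## survival: hazard class from the within-type 80th percentile of true counts
  sv <- cfg$survival_model
  patients[, hazard_class := classify_high_low(true_n_variants, 80),
           by = cancer_type]
  os <- patients[, {
    t_evt <- vapply(seq_len(.N), function(j) {
      .with_seed(derive_seed(cfg$seed, paste0(patient[j], ":surv")), {
        haz <- sv[["baseline_hazard"]] *
          ifelse(hazard_class[j], sv[["hr_high_tmb"]], 1)
        evt <- stats::rexp(1L, haz)
        cns <- stats::runif(1L, 0, 2 * cfg$censor_horizon)
        c(min(evt, cns, cfg$censor_horizon),
          as.integer(evt <= cns & evt <= cfg$censor_horizon))
      })
    }, numeric(2))
    .(patient = patient, os_time = t_evt[1, ], os_event = as.integer(t_evt[2, ]))
  }]
  patients <- merge(patients, os, by = "patient", sort = FALSE)
  hc <- stats::setNames(patients$hazard_class, patients$patient)
  for (pid in names(truth)) {
    truth[[pid]]$hazard_class <- unname(hc[[pid]])
  }

  ## transcript/intron quantifications for the RI analysis cohort
  rna_quants <- .generate_rna_quants(cfg, shared, patients, truth)
  truth <- rna_quants$truth

  structure(list(
    config = cfg,
    patients = patients,
    samples = data.table::rbindlist(sample_rows),
    hla = data.table::rbindlist(hla_rows),
    coverage = data.table::rbindlist(coverage_rows),
    calls = data.table::rbindlist(Filter(Negate(is.null), call_rows)),
    truth_variants = data.table::rbindlist(truth_var_rows),
    peptides = data.table::rbindlist(Filter(Negate(is.null), peptide_rows)),
    binding = data.table::rbindlist(Filter(Negate(is.null), binding_rows)),
    junctions = data.table::rbindlist(Filter(Negate(is.null), jx_rows)),
    normal_junctions = shared$compendium_jx,
    tcga_quantiles = shared$tcga,
    transcript_quants = rna_quants$quants,
    intron_counts = rna_quants$intron_counts,
    normal_intron_counts = rna_quants$normal_intron_counts,
    exon_coverage = rna_quants$exon_coverage,
    intron_seqs = rna_quants$intron_seqs,
    truth = truth
  ), class = "tvb_cohort")
}

## per-sample transcript quantifications and intron count tables, with
## retained-intron outliers planted for RI-positive patients
.generate_rna_quants <- function(cfg, shared, patients, truth) {
  ri_pats <- patients[cancer_type %in% cfg$ri_types & has_rna == TRUE, patient]
  empty <- list(
    quants = data.table::data.table(transcript = character(),
                                    sample_id = character(), tpm = numeric(),
                                    unique_counts = integer(),
                                    retention_frac = numeric()),
    intron_counts = data.table::data.table(patient = character(),
                                           transcript = character(),
                                           intron_index = integer(),
                                           count = integer(),
                                           transcript_count = integer()),
    normal_intron_counts = NULL, exon_coverage = NULL, intron_seqs = NULL,
    truth = truth)
  rna_pats <- patients[has_rna == TRUE, patient]
  if (length(rna_pats) == 0L) return(empty)

  tx <- shared$transcripts
  n_tx <- length(tx)
  n_in <- shared$n_introns

  out <- .with_seed(derive_seed(cfg$seed, "rna"), {
    quants <- list(); intron_counts <- list(); exon_cov <- list()
    ri_truth <- list()
    ## ~60% of transcripts are cohort-expressed with partial retention;
    ## a tenth of the expressed pool is reserved for normal-tissue RIs so
    ## tumor-planted and normal-planted introns never collide
    expressed <- stats::runif(n_tx) < 0.6
    normal_reserved <- sample(tx[expressed],
                              max(1L, round(0.1 * sum(expressed))))
    tumor_plantable <- setdiff(tx[expressed], normal_reserved)
    for (pid in rna_pats) {
      tpm <- ifelse(expressed, stats::rlnorm(n_tx, log(8), 1),
                    stats::rlnorm(n_tx, log(0.2), 0.5))
      uc <- stats::rpois(n_tx, ifelse(expressed, 40, 2))
      rf <- ifelse(expressed, stats::runif(n_tx, 0.05, 0.6), 0)
      quants[[pid]] <- data.table::data.table(
        transcript = tx, sample_id = pid, tpm = tpm,
        unique_counts = uc, retention_frac = rf)
      exon_cov[[pid]] <- data.table::data.table(
        patient = pid, transcript = tx,
        max_reads = stats::rpois(n_tx, ifelse(expressed, 12, 0.4)))
      if (pid %in% ri_pats) {
        is_ri_pos <- stats::runif(1L) <= cfg$ri_fraction
        counts <- data.table::data.table(
          patient = pid,
          transcript = rep(tx, n_in),
          intron_index = unlist(lapply(n_in, seq_len)),
          count = stats::rpois(sum(n_in), 5),
          transcript_count = rep(stats::rpois(n_tx, 30), n_in))
        ri_keys <- character(0)
        if (is_ri_pos) {
          rl <- cfg$ri_lognormal
          n_ri <- min(length(tumor_plantable),
                      max(1L, as.integer(round(
                        stats::rlnorm(1L, rl[["meanlog"]], rl[["sdlog"]])))))
          ri_tx <- sample(tumor_plantable, n_ri)
          plant_idx <- counts[, .I[transcript %in% ri_tx & intron_index == 1L]]
          ## outlier: far above median + 3 MAD and >= the transcript count
          counts[plant_idx,
                 count := pmax(transcript_count, 5L + 60L) +
                   stats::rpois(length(plant_idx), 10)]
          ri_keys <- paste(ri_tx, 1L, sep = ":")
        }
        intron_counts[[pid]] <- counts
        ri_truth[[pid]] <- ri_keys
      }
    }
    ## melanocyte-style normal samples with planted normal RIs on the
    ## reserved transcripts (removed from tumor RI sets downstream)
    normal_counts <- data.table::data.table(
      sample_id = "melanocyte_01",
      transcript = rep(tx, n_in),
      intron_index = unlist(lapply(n_in, seq_len)),
      count = stats::rpois(sum(n_in), 5),
      transcript_count = rep(stats::rpois(n_tx, 30), n_in))
    normal_plant <- normal_counts[, .I[transcript %in% normal_reserved &
                                         intron_index == 1L]]
    normal_counts[normal_plant,
                  count := pmax(transcript_count, 65L) +
                    stats::rpois(length(normal_plant), 10)]
    ## nucleotide sequences for the plantable intron (index 1) of every
    ## expressed transcript: an in-frame stop-free upstream CDS plus the
    ## intron itself, for retained-intron peptide enumeration
    non_stop <- setdiff(as.vector(outer(outer(c("A","C","G","T"), c("A","C","G","T"),
                                              paste0), c("A","C","G","T"), paste0)),
                        c("TAA", "TAG", "TGA"))
    seq_tx <- tx[expressed]
    intron_seqs <- data.table::data.table(
      transcript = seq_tx, intron_index = 1L,
      upstream_cds = vapply(seq_along(seq_tx), function(j)
        paste(sample(non_stop, 15L, replace = TRUE), collapse = ""), character(1)),
      intron_seq = .random_bases(length(seq_tx), len = 75L))
    list(quants = data.table::rbindlist(quants),
         intron_counts = if (length(intron_counts))
           data.table::rbindlist(intron_counts) else empty$intron_counts,
         normal_intron_counts = normal_counts,
         exon_coverage = data.table::rbindlist(exon_cov),
         intron_seqs = intron_seqs,
         ri_truth = ri_truth)
  })
  for (pid in names(out$ri_truth)) {
    truth[[pid]]$true_ri_keys <- out$ri_truth[[pid]]
  }
  list(quants = out$quants, intron_counts = out$intron_counts,
       normal_intron_counts = out$normal_intron_counts,
       exon_coverage = out$exon_coverage, intron_seqs = out$intron_seqs,
       truth = truth)
}

#' Generate a synthetic proteome and protein-level variants
#'
#' Builds random protein sequences and places substitution / insertion /
#' deletion variants at recorded protein coordinates, deterministically under
#' the seed. Used to exercise peptide enumeration and the closest-normal
#' search end-to-end.
#'
#' @param n_proteins number of proteins.
#' @param lengths range (min, max) of protein lengths; at least 25 recommended
#'   so full 8-24-mer windows exist.
#' @param n_variants number of variants to place (at distinct positions).
#' @param seed integer seed.
#' @return list with `proteome` (named character vector), `variants`
#'   (data.table: variant_id, protein_id, position, ref_aa, alt_aa, vclass).
#' @export
generate_proteome_and_variants <- function(n_proteins, lengths, n_variants,
                                           seed) {
  .assert(.is_count(n_proteins) && n_proteins >= 1L, "need at least one protein")
  lengths <- range(lengths)
  .with_seed(derive_seed(seed, "proteome"), {
    lens <- if (lengths[1] == lengths[2]) rep(lengths[1], n_proteins)
            else sample(lengths[1]:lengths[2], n_proteins, replace = TRUE)
    prots <- stats::setNames(.random_peptide(n_proteins, lens),
                             sprintf("PROT%04d", seq_len(n_proteins)))
    slots <- data.table::rbindlist(lapply(names(prots), function(id)
      data.table::data.table(protein_id = id,
                             position = seq_len(nchar(prots[[id]])))))
    .assert(n_variants <= nrow(slots),
            "n_variants exceeds the number of available protein positions")
    if (n_variants == 0L) {
      return(list(proteome = prots,
                  variants = data.table::data.table(
                    variant_id = character(), protein_id = character(),
                    position = integer(), ref_aa = character(),
                    alt_aa = character(), vclass = character())))
    }
    picked <- slots[sample.int(nrow(slots), n_variants)]
    cls <- sample(c("substitution", "insertion", "deletion"), n_variants,
                  replace = TRUE, prob = c(0.85, 0.075, 0.075))
    ref <- substring(prots[picked$protein_id], picked$position, picked$position)
    alt <- vapply(seq_len(n_variants), function(j) {
      switch(cls[j],
             substitution = sample(setdiff(.amino_acids, ref[j]), 1L),
             insertion = paste0(ref[j],
                                paste(sample(.amino_acids,
                                             sample(1:3, 1L),
                                             replace = TRUE), collapse = "")),
             deletion = "")
    }, character(1))
    list(proteome = prots,
         variants = data.table::data.table(
           variant_id = sprintf("VAR%04d", seq_len(n_variants)),
           protein_id = picked$protein_id, position = picked$position,
           ref_aa = ref, alt_aa = alt, vclass = cls))
  })
}

#' Apply a protein-level variant to its protein sequence
#'
#' @param protein the reference protein sequence.
#' @param variant one row of the variant table from
#'   [generate_proteome_and_variants()].
#' @return list with `sequence` (mutated protein) and `altered_position`
#'   (position of the changed residue; for deletions, the residue following
#'   the deleted one, capped at the new protein length).
#' @export
apply_protein_variant <- function(protein, variant) {
  p <- variant$position
  n <- nchar(protein)
  .assert(p >= 1L && p <= n, "variant position out of protein range")
  pre <- substring(protein, 1L, p - 1L)
  post <- substring(protein, p + 1L, n)
  mutated <- paste0(pre, variant$alt_aa, post)
  list(sequence = mutated,
       altered_position = min(max(1L, p), nchar(mutated)))
}

#' Write a FASTA file from a named character vector
#'
#' @param sequences named character vector of sequences.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_fasta <- function(sequences, path) {
  Biostrings::writeXStringSet(
    Biostrings::AAStringSet(sequences), filepath = path)
  invisible(path)
}

#' Read protein sequences from a FASTA file
#'
#' @param path path to a FASTA file.
#' @return named character vector of sequences.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readAAStringSet(path)
  stats::setNames(as.character(x), names(x))
}
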