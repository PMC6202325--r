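# Synthetic-data generator: genomes, gene models, domain tables, fusion
# candidates with known truth labels, exon expression matrices and clinical
# cohorts. The defaults emulate the study geometry this package targets:
# 384 diffuse gastric cancers, three recurrent fusions carried by 13/2/2
# samples, fusion-mutation mutual exclusivity, 3'-of-breakpoint
# overexpression in carriers, and exponential survival with a hazard ratio
# of 2.8 for fusion carriers against a 94.6-month baseline median.
#
# Randomness: a single integer seed governs everything. Each top-level
# generator seeds its own stream at a fixed offset from it (reference +0,
# fusions +1, expression +2, cohort +3), so stages can be re-run
# independently and still reproduce byte-identical output.

#' Simulation configuration
#'
#' Collects every tunable of the synthetic-data generator with defaults
#' mirroring the targeted study design.
#'
#' @param seed Integer master seed.
#' @param n_genes Number of genes in the synthetic reference.
#' @param exons_per_gene Length-2 integer range of exon counts.
#' @param exon_length Length-2 range of exon lengths (nt).
#' @param intron_length Length-2 range of intron lengths (nt).
#' @param utr5_length,utr3_length Length-2 ranges for untranslated ends (nt).
#' @param strand_fraction_minus Fraction of genes placed on the minus strand.
#' @param n_samples Cohort size (default 384).
#' @param fusions Data frame with columns `gene5`, `gene3`, `n_carriers`,
#'   `breakpoint_type` (`"intronic"`/`"exonic"`), `truth_frame`
#'   (`"in_frame"`/`"frameshift"`/`"promoter_swap"`). Gene names refer to
#'   the synthetic genes `G01`, `G02`, ... Default: three in-frame fusions
#'   carried by 13, 2 and 2 samples.
#' @param n_decoys Sub-threshold decoy candidates to add (spanning reads
#'   <= 3).
#' @param expression_effect Log2-units added to 3'-of-breakpoint exons of
#'   the 3' partner in carriers (default 3).
#' @param expression_sd Exon-level log2 noise SD.
#' @param mutual_exclusivity Draw CDH1/RHOA mutation flags mutually
#'   exclusive with fusion carriers (default TRUE).
#' @param mutation_rates Named vector of per-sample mutation/flag
#'   probabilities among fusion-negative samples.
#' @param n_sequenced Number of samples with non-missing mutation flags
#'   (carriers are always sequenced).
#' @param baseline_median Baseline median survival in months (default 94.6).
#' @param hazard_ratios Named vector of per-flag hazard ratios applied
#'   multiplicatively (names match cohort columns; `"fusion"` means any
#'   fusion carrier).
#' @param admin_censor_months Administrative censoring horizon (months).
#' @param dropout_fraction Fraction of patients with an additional uniform
#'   dropout censoring time.
#' @param carriers_younger Bias carrier ages younger (default TRUE).
#' @return Object of class `sim_config` (a validated list).
#' @export
sim_config <- function(seed = 1L,
                       n_genes = 12L,
                       exons_per_gene = c(4L, 8L),
                       exon_length = c(90L, 240L),
                       intron_length = c(150L, 600L),
                       utr5_length = c(30L, 90L),
                       utr3_length = c(60L, 150L),
                       strand_fraction_minus = 0.4,
                       n_samples = 384L,
                       fusions = NULL,
                       n_decoys = 6L,
                       expression_effect = 3,
                       expression_sd = 0.5,
                       mutual_exclusivity = TRUE,
                       mutation_rates = c(CDH1 = 0.31, RHOA = 0.15,
                                          TP53 = 0.40, CIN = 0.35),
                       n_sequenced = 229L,
                       baseline_median = 94.6,
                       hazard_ratios = c(fusion = 2.8),
                       admin_censor_months = 120,
                       dropout_fraction = 0.2,
                       carriers_younger = TRUE) {
  if (is.null(fusions)) {
    fusions <- data.frame(
      gene5 = c("G01", "G03", "G05"),
      gene3 = c("G02", "G02", "G06"),
      n_carriers = c(13L, 2L, 2L),
      breakpoint_type = c("exonic", "intronic", "intronic"),
      truth_frame = c("in_frame", "in_frame", "in_frame"),
      stringsAsFactors = FALSE
    )
  }
  cfg <- list(
    seed = as.integer(seed), n_genes = as.integer(n_genes),
    exons_per_gene = as.integer(exons_per_gene),
    exon_length = as.integer(exon_length),
    intron_length = as.integer(intron_length),
    utr5_length = as.integer(utr5_length),
    utr3_length = as.integer(utr3_length),
    strand_fraction_minus = strand_fraction_minus,
    n_samples = as.integer(n_samples), fusions = fusions,
    n_decoys = as.integer(n_decoys),
    expression_effect = expression_effect, expression_sd = expression_sd,
    mutual_exclusivity = isTRUE(mutual_exclusivity),
    mutation_rates = mutation_rates, n_sequenced = as.integer(n_sequenced),
    baseline_median = baseline_median, hazard_ratios = hazard_ratios,
    admin_censor_months = admin_censor_months,
    dropout_fraction = dropout_fraction,
    carriers_younger = isTRUE(carriers_younger)
  )
  if (any(cfg$exon_length <= 0) || any(cfg$intron_length <= 0)) {
    ff_stop("infeasible exon/intron length range")
  }
  if (any(fusions$n_carriers > cfg$n_samples)) {
    ff_stop("n_carriers exceeds n_samples")
  }
  structure(cfg, class = "sim_config")
}

sample_range <- function(rng, n = 1L) {
  if (rng[1L] == rng[2L]) rep(rng[1L], n) else sample(rng[1L]:rng[2L], n, replace = TRUE)
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# Random open reading frame: ATG + n_codons sense codons + one stop.
NON_STOP_CODONS <- local({
  b <- c("A", "C", "G", "T")
  all <- as.vector(outer(outer(b, b, paste0), b, paste0))
  setdiff(all, c("TAA", "TAG", "TGA"))
})

random_orf <- function(n_codons) {
  paste0("ATG",
         paste(sample(NON_STOP_CODONS, n_codons - 1L, replace = TRUE),
               collapse = ""),
         sample(c("TAA", "TAG", "TGA"), 1L))
}

#' Simulate a synthetic reference: genome, transcript models, domains
#'
#' Generates `n_genes` non-overlapping genes (`G01`, `G02`, ...) on one
#' contig, each with a multi-exon coding transcript: a 5' UTR, a CDS with
#' start and stop codons and no internal stop, and a 3' UTR, split across
#' exons with intervening introns. Genes fall on either strand. Protein
#' domains are placed at known amino-acid intervals; the default genes
#' `G02` and `G06` carry a `RhoGAP` and a `PAP2` domain respectively, near
#' the C-terminus so that 3'-retained fusions keep them.
#'
#' @param config A [sim_config()].
#' @return List with `genome` (`genome_sequence`), `models` (named list of
#'   `transcript_model`) and `domains` (data frame).
#' @export
simulate_reference <- function(config) {
  set.seed(config$seed)
  n <- config$n_genes
  contig <- "chrS1"
  pieces <- character(0)
  pos <- 1L
  models <- list()
  domain_rows <- list()
  gene_names <- sprintf("G%02d", seq_len(n))
  for (gi in seq_len(n)) {
    gene <- gene_names[gi]
    n_ex <- sample_range(config$exons_per_gene)
    ex_len <- sample_range(config$exon_length, n_ex)
    in_len <- sample_range(config$intron_length, max(0L, n_ex - 1L))
    tlen <- sum(ex_len)
    utr5 <- sample_range(config$utr5_length)
    utr3 <- sample_range(config$utr3_length)
    cds_len <- tlen - utr5 - utr3
    cds_len <- cds_len - cds_len %% 3L
    if (cds_len < 60L) {
      # stretch the last exon so the gene stays comfortably coding
      ex_len[n_ex] <- ex_len[n_ex] + (60L - cds_len)
      tlen <- sum(ex_len)
      cds_len <- tlen - utr5 - utr3
      cds_len <- cds_len - cds_len %% 3L
    }
    utr3 <- tlen - utr5 - cds_len  # absorb the modulo remainder
    spliced <- paste0(random_dna(utr5), random_orf(cds_len %/% 3L - 1L),
                      random_dna(utr3))
    stopifnot(nchar(spliced) == tlen)
    # interleave exons and introns into the genomic (pre-mRNA) sequence
    ex_start_t <- cumsum(c(1L, ex_len))[seq_len(n_ex)]
    ex_seq <- substring(spliced, ex_start_t, ex_start_t + ex_len - 1L)
    premrna <- character(2L * n_ex - 1L)
    premrna[seq(1L, 2L * n_ex - 1L, by = 2L)] <- ex_seq
    if (n_ex > 1L) {
      premrna[seq(2L, 2L * n_ex - 2L, by = 2L)] <-
        vapply(in_len, random_dna, "")
    }
    gseq <- paste(premrna, collapse = "")
    glen <- nchar(gseq)
    strand <- if (runif(1) < config$strand_fraction_minus) "-" else "+"
    # transcript-orientation offsets of the exons within the pre-mRNA
    piece_len <- c(rbind(ex_len, c(in_len, NA)))
    piece_len <- piece_len[!is.na(piece_len)]
    piece_end <- cumsum(piece_len)
    ex_a <- piece_end[seq(1L, length(piece_len), by = 2L)] -
      ex_len + 1L
    ex_b <- piece_end[seq(1L, length(piece_len), by = 2L)]
    if (strand == "+") {
      exons <- data.frame(start = pos + ex_a - 1L, end = pos + ex_b - 1L)
      pieces <- c(pieces, gseq)
    } else {
      gseq_rc <- as.character(
        Biostrings::reverseComplement(Biostrings::DNAString(gseq))
      )
      exons <- data.frame(start = pos + glen - ex_b, end = pos + glen - ex_a)
      pieces <- c(pieces, gseq_rc)
    }
    models[[paste0(gene, ".t1")]] <- transcript_model(
      gene_id = gene, gene_name = gene, transcript_id = paste0(gene, ".t1"),
      contig = contig, strand = strand, exons = exons,
      cds_start = utr5 + 1L, cds_end = utr5 + cds_len
    )
    # one domain per gene at a known aa interval; RhoGAP / PAP2 land near
    # the C-terminus of the designated 3'-partner genes
    n_aa <- cds_len %/% 3L - 1L
    dom_name <- if (gene == "G02") "RhoGAP" else if (gene == "G06") "PAP2"
      else sample(c("Arm", "C1", "coiled-coil", "SH3", "kinase"), 1L)
    dom_start <- if (dom_name %in% c("RhoGAP", "PAP2")) {
      max(2L, n_aa - max(10L, n_aa %/% 3L))
    } else {
      max(2L, sample.int(max(2L, n_aa %/% 2L), 1L))
    }
    dom_end <- min(n_aa - 1L, dom_start + max(5L, n_aa %/% 5L))
    domain_rows[[gi]] <- data.frame(
      gene_name = gene, domain_name = dom_name,
      aa_start = dom_start, aa_end = dom_end, stringsAsFactors = FALSE
    )
    spacer <- random_dna(sample_range(c(200L, 500L)))
    pieces <- c(pieces, spacer)
    pos <- pos + glen + nchar(spacer)
  }
  genome <- if (n == 0L) {
    structure(list(), class = "genome_sequence")
  } else {
    structure(setNames(list(paste(pieces, collapse = "")), contig),
              class = "genome_sequence")
  }
  domains <- if (n == 0L) {
    data.frame(gene_name = character(), domain_name = character(),
               aa_start = integer(), aa_end = integer(),
               stringsAsFactors = FALSE)
  } else {
    do.call(rbind, domain_rows)
  }
  list(genome = genome, models = models, domains = domains)
}

# Transcript coordinates of exon boundaries (in transcript orientation).
exon_boundaries_t <- function(model) {
  ex <- exons_in_transcript_order(model)
  widths <- ex$end - ex$start + 1L
  list(last = cumsum(widths),                      # last base of exon i
       first = cumsum(c(1L, widths))[seq_len(nrow(ex))])  # first base of exon i
}

# Exon index (transcript orientation) containing transcript position tpos.
exon_index_of_tpos <- function(model, tpos) {
  b <- exon_boundaries_t(model)
  which(tpos >= b$first & tpos <= b$last)[1L]
}

#' Simulate fusion candidates with known truth labels
#'
#' For each configured fusion, breakpoints are chosen so that the correct
#' frame call is the requested truth label (by picking breakpoint phases;
#' verified against [classify_frame()] at generation time). Carriers get
#' supra-threshold spanning-read counts; sub-threshold decoy candidates on
#' random gene pairs are added.
#'
#' @param config A [sim_config()].
#' @param reference Output of [simulate_reference()].
#' @return List with `candidates` (data frame in [read_candidates()]
#'   layout plus `truth` label) and `truth` (one row per planted fusion:
#'   genes, sample carriers, truth frame, and `k3`, the first retained
#'   exon index of the 3' partner, used for expression planting).
#' @export
simulate_fusions <- function(config, reference) {
  set.seed(config$seed + 1L)
  models <- reference$models
  genome <- reference$genome
  sample_ids <- sprintf("S%03d", seq_len(config$n_samples))
  cand_rows <- list()
  truth_rows <- list()
  taken <- character(0)  # carriers already used, to keep fusions disjoint
  for (fi in seq_len(nrow(config$fusions))) {
    spec <- config$fusions[fi, ]
    m5 <- canonical_for_gene(models, spec$gene5)
    m3 <- canonical_for_gene(models, spec$gene3)
    bp <- pick_breakpoints(m5, m3, spec$truth_frame, spec$breakpoint_type,
                           genome)
    carriers <- sample(setdiff(sample_ids, taken), spec$n_carriers)
    taken <- c(taken, carriers)
    k3 <- exon_index_of_tpos(m3, bp$t3)
    cand_rows[[length(cand_rows) + 1L]] <- data.frame(
      sample_id = carriers,
      gene5 = spec$gene5, contig5 = m5$contig, pos5 = bp$gpos5,
      gene3 = spec$gene3, contig3 = m3$contig, pos3 = bp$gpos3,
      spanning_reads = sample(4:50, spec$n_carriers, replace = TRUE),
      provenance = "genomic", caller = "simulated",
      truth = spec$truth_frame, stringsAsFactors = FALSE
    )
    truth_rows[[fi]] <- data.frame(
      fusion = paste0(spec$gene5, "-", spec$gene3),
      gene5 = spec$gene5, gene3 = spec$gene3,
      carriers = paste(sort(carriers), collapse = ","),
      n_carriers = spec$n_carriers, truth_frame = spec$truth_frame,
      k3 = k3, stringsAsFactors = FALSE
    )
  }
  # sub-threshold decoys: random coding-gene pairs, 0-3 spanning reads
  gene_names <- unique(vapply(models, `[[`, "", "gene_name"))
  for (di in seq_len(config$n_decoys)) {
    pair <- sample(gene_names, 2L)
    m5 <- canonical_for_gene(models, pair[1L])
    m3 <- canonical_for_gene(models, pair[2L])
    bp <- pick_breakpoints(m5, m3, "any", "exonic", genome)
    cand_rows[[length(cand_rows) + 1L]] <- data.frame(
      sample_id = sample(sample_ids, 1L),
      gene5 = pair[1L], contig5 = m5$contig, pos5 = bp$gpos5,
      gene3 = pair[2L], contig3 = m3$contig, pos3 = bp$gpos3,
      spanning_reads = sample(0:3, 1L),
      provenance = "genomic", caller = "simulated",
      truth = "decoy", stringsAsFactors = FALSE
    )
  }
  candidates <- do.call(rbind, cand_rows)
  rownames(candidates) <- NULL
  list(candidates = candidates, truth = do.call(rbind, truth_rows))
}

# Choose mRNA-level breakpoints realising the requested frame truth, then
# (for intronic type) push the reported genomic coordinates into the
# adjacent introns so intake has to resolve them through
# infer_mrna_breakpoint().
pick_breakpoints <- function(m5, m3, truth, type, genome, max_tries = 200L) {
  b5 <- exon_boundaries_t(m5)
  b3 <- exon_boundaries_t(m3)
  n_ex5 <- length(b5$last)
  n_ex3 <- length(b3$last)
  t5_pool <- if (type == "intronic") {
    b5$last[-n_ex5]  # exon ends that are followed by an intron
  } else {
    NULL             # sampled per try
  }
  t3_pool <- if (type == "intronic") b3$first[-1L] else NULL
  for (try in seq_len(max_tries)) {
    if (truth == "promoter_swap") {
      if (m5$cds_start < 2L) ff_stop(paste0(
        "promoter_swap impossible: ", m5$gene_name, " has no 5' UTR"))
      t5 <- sample.int(m5$cds_start - 1L, 1L)
      t3 <- sample.int(m3$cds_start, 1L)
      if (type == "intronic") {
        t5c <- t5_pool[t5_pool < m5$cds_start]
        t3c <- t3_pool[t3_pool <= m3$cds_start]
        if (!length(t5c) || !length(t3c)) {
          ff_stop("promoter_swap impossible with intronic breakpoints for this gene pair")
        }
        t5 <- sample(rep(t5c, 2L), 1L)
        t3 <- sample(rep(t3c, 2L), 1L)
      }
    } else {
      t5 <- if (type == "intronic") {
        pool <- t5_pool[t5_pool >= m5$cds_start & t5_pool < m5$cds_end - 3L]
        if (!length(pool)) ff_stop("no usable 5' exon boundary inside the CDS")
        sample(rep(pool, 2L), 1L)
      } else {
        sample(seq(m5$cds_start, m5$cds_end - 4L), 1L)
      }
      t3 <- if (type == "intronic") {
        pool <- t3_pool[t3_pool > m3$cds_start & t3_pool <= m3$cds_end - 6L]
        if (!length(pool)) ff_stop("no usable 3' exon boundary inside the CDS")
        sample(rep(pool, 2L), 1L)
      } else {
        # stay out of the first exon so the 3' partner keeps upstream exons
        # against which breakpoint expression imbalance can be scored
        first2 <- exon_boundaries_t(m3)$first[2L]
        lo <- max(m3$cds_start + 1L, if (is.na(first2)) 0L else first2)
        if (lo > m3$cds_end - 6L) lo <- m3$cds_start + 1L
        sample(seq(lo, m3$cds_end - 6L), 1L)
      }
    }
    gpos5 <- transcript_to_genomic(m5, t5)
    gpos3 <- transcript_to_genomic(m3, t3)
    status <- classify_frame(m5, gpos5, m3, gpos3, genome)$status
    ok <- switch(truth,
      in_frame = status == "IN_FRAME",
      frameshift = status == "FRAMESHIFT",
      promoter_swap = status == "PROMOTER_SWAP",
      any = TRUE
    )
    if (ok) {
      if (type == "intronic") {
        gpos5 <- intronic_gpos_after_exon(m5, t5)
        gpos3 <- intronic_gpos_before_exon(m3, t3)
      }
      return(list(gpos5 = gpos5, gpos3 = gpos3, t5 = t5, t3 = t3))
    }
  }
  ff_stop(sprintf("could not realise truth '%s' for %s-%s in %d tries",
                  truth, m5$gene_name, m3$gene_name, max_tries))
}

# A genomic position strictly inside the intron following the exon whose
# last transcript base is t5.
intronic_gpos_after_exon <- function(model, t5) {
  i <- exon_index_of_tpos(model, t5)
  ex <- exons_in_transcript_order(model)
  if (model$strand == "+") {
    ex$end[i] + max(1L, (ex$start[i + 1L] - ex$end[i]) %/% 2L)
  } else {
    ex$start[i] - max(1L, (ex$start[i] - ex$end[i + 1L]) %/% 2L)
  }
}

# A genomic position strictly inside the intron preceding the exon whose
# first transcript base is t3.
intronic_gpos_before_exon <- function(model, t3) {
  i <- exon_index_of_tpos(model, t3)
  ex <- exons_in_transcript_order(model)
  if (model$strand == "+") {
    ex$start[i] - max(1L, (ex$start[i] - ex$end[i - 1L]) %/% 2L)
  } else {
    ex$end[i] + max(1L, (ex$start[i - 1L] - ex$end[i]) %/% 2L)
  }
}

#' Simulate an exon-level expression matrix
#'
#' Baseline log2 FPKM per exon is normal around a per-gene mean; fusion
#' carriers receive `expression_effect` extra log2-units on the 3'-partner
#' exons at and downstream of the first retained exon, emulating
#' breakpoint-consistent 3' overexpression driven by the 5' promoter.
#'
#' @param config A [sim_config()].
#' @param reference Output of [simulate_reference()].
#' @param fusion_truth `truth` element of [simulate_fusions()] (or `NULL`
#'   for a pure null matrix).
#' @return An `exon_matrix` of FPKM values.
#' @export
simulate_expression <- function(config, reference, fusion_truth = NULL) {
  set.seed(config$seed + 2L)
  models <- reference$models
  sample_ids <- sprintf("S%03d", seq_len(config$n_samples))
  rows <- do.call(rbind, lapply(models, function(m) {
    ex <- exons_in_transcript_order(m)
    data.frame(gene = m$gene_name, exon_index = seq_len(nrow(ex)),
               contig = m$contig, start = ex$start, end = ex$end,
               stringsAsFactors = FALSE)
  }))
  rownames(rows) <- NULL
  gene_mean <- setNames(runif(length(models), 2, 8),
                        vapply(models, `[[`, "", "gene_name"))
  exon_shift <- rnorm(nrow(rows), 0, 0.3)  # fixed per-exon offset
  log2fpkm <- matrix(
    gene_mean[rows$gene] + exon_shift +
      rnorm(nrow(rows) * length(sample_ids), 0, config$expression_sd),
    nrow = nrow(rows), ncol = length(sample_ids),
    dimnames = list(NULL, sample_ids)
  )
  if (!is.null(fusion_truth) && nrow(fusion_truth) > 0L) {
    for (fi in seq_len(nrow(fusion_truth))) {
      tr <- fusion_truth[fi, ]
      carriers <- strsplit(tr$carriers, ",", fixed = TRUE)[[1L]]
      hit <- rows$gene == tr$gene3 & rows$exon_index >= tr$k3
      log2fpkm[hit, carriers] <- log2fpkm[hit, carriers] +
        config$expression_effect
    }
  }
  exon_matrix(rows, 2^log2fpkm)
}

#' Simulate a clinical cohort with survival outcomes
#'
#' Fusion-status columns come from the planted truth (or are drawn to the
#' configured carrier counts when no truth is supplied). Mutation flags
#' (CDH1, RHOA, TP53) and the CIN flag are Bernoulli within the sequenced
#' subset; when `mutual_exclusivity` is on, CDH1 and RHOA mutations never
#' co-occur with a fusion. Survival times are exponential with hazard
#' `log(2) / baseline_median` times the product of the configured hazard
#' ratios over the sample's positive flags; censoring is administrative at
#' `admin_censor_months` with an additional uniform dropout for a
#' configurable fraction of patients. Carrier ages can be biased younger.
#'
#' @param config A [sim_config()].
#' @param fusion_truth `truth` element of [simulate_fusions()], or `NULL`.
#' @return Cohort data frame (one row per sample) with `sample_id`, `age`,
#'   `onset_class`, one `fusion_<NAME>` column per planted fusion,
#'   `fusion_any`, mutation/CIN flags (NA outside the sequenced subset),
#'   `survival_months` and `event`.
#' @export
simulate_cohort <- function(config, fusion_truth = NULL) {
  set.seed(config$seed + 3L)
  n <- config$n_samples
  sample_ids <- sprintf("S%03d", seq_len(n))
  cohort <- data.frame(sample_id = sample_ids, stringsAsFactors = FALSE)
  fusion_cols <- character(0)
  if (is.null(fusion_truth)) {
    taken <- character(0)
    truth_rows <- lapply(seq_len(nrow(config$fusions)), function(fi) {
      spec <- config$fusions[fi, ]
      carriers <- sample(setdiff(sample_ids, taken), spec$n_carriers)
      taken <<- c(taken, carriers)
      data.frame(fusion = paste0(spec$gene5, "-", spec$gene3),
                 carriers = paste(sort(carriers), collapse = ","),
                 stringsAsFactors = FALSE)
    })
    fusion_truth <- do.call(rbind, truth_rows)
  }
  for (fi in seq_len(nrow(fusion_truth))) {
    col <- paste0("fusion_", fusion_truth$fusion[fi])
    carriers <- strsplit(fusion_truth$carriers[fi], ",", fixed = TRUE)[[1L]]
    cohort[[col]] <- cohort$sample_id %in% carriers
    fusion_cols <- c(fusion_cols, col)
  }
  cohort$fusion_any <- rowSums(as.matrix(cohort[, fusion_cols, drop = FALSE])) > 0
  # ages: carriers optionally biased younger (early-onset enrichment)
  age <- round(rnorm(n, 58, 10))
  if (config$carriers_younger) {
    age[cohort$fusion_any] <- round(rnorm(sum(cohort$fusion_any), 45, 10))
  }
  cohort$age <- pmin(pmax(age, 22), 90)
  cohort$onset_class <- ifelse(cohort$age <= 45, "early", "late")
  # molecular flags within the sequenced subset
  neg_pool <- cohort$sample_id[!cohort$fusion_any]
  n_extra <- min(length(neg_pool),
                 max(0L, config$n_sequenced - sum(cohort$fusion_any)))
  sequenced <- cohort$sample_id %in%
    c(cohort$sample_id[cohort$fusion_any], sample(neg_pool, n_extra))
  for (flag in names(config$mutation_rates)) {
    val <- rbinom(n, 1L, config$mutation_rates[[flag]]) == 1L
    if (config$mutual_exclusivity && flag %in% c("CDH1", "RHOA")) {
      val[cohort$fusion_any] <- FALSE
    }
    val[!sequenced] <- NA
    cohort[[flag]] <- val
  }
  # exponential survival under multiplicative proportional hazards
  h0 <- log(2) / config$baseline_median
  log_hr <- rep(0, n)
  for (flag in names(config$hazard_ratios)) {
    ind <- if (flag == "fusion") cohort$fusion_any else cohort[[flag]] %in% TRUE
    log_hr <- log_hr + ind * log(config$hazard_ratios[[flag]])
  }
  t_event <- rexp(n, rate = h0 * exp(log_hr))
  cens <- rep(config$admin_censor_months, n)
  dropout <- runif(n) < config$dropout_fraction
  cens[dropout] <- pmin(cens[dropout],
                        runif(sum(dropout), 0, config$admin_censor_months))
  cohort$survival_months <- round(pmin(t_event, cens), 1)
  cohort$event <- t_event <= cens
  cohort
}

#' Generate and write a complete synthetic dataset
#'
#' Runs all four generators and writes FASTA, GTF, domain TSV, candidate
#' TSV, exon-matrix TSV and cohort TSV into `outdir`.
#'
#' @param config A [sim_config()].
#' @param outdir Output directory (created if missing).
#' @return Invisibly, a named list of the written file paths plus the
#'   in-memory objects.
#' @export
simulate_dataset <- function(config, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  ref <- simulate_reference(config)
  fus <- simulate_fusions(config, ref)
  expr <- simulate_expression(config, ref, fus$truth)
  cohort <- simulate_cohort(config, fus$truth)
  paths <- list(
    genome = file.path(outdir, "genome.fa"),
    gtf = file.path(outdir, "models.gtf"),
    domains = file.path(outdir, "domains.tsv"),
    candidates = file.path(outdir, "candidates.tsv"),
    exon_matrix = file.path(outdir, "exon_matrix.tsv"),
    cohort = file.path(outdir, "cohort.tsv"),
    truth = file.path(outdir, "fusion_truth.tsv")
  )
  write_genome(ref$genome, paths$genome)
  write_gene_models(ref$models, paths$gtf)
  write_domain_table(ref$domains, paths$domains)
  write_candidates(fus$candidates, paths$candidates)
  write_exon_matrix(expr, paths$exon_matrix)
  write_cohort(cohort, paths$cohort)
  write.table(fus$truth, paths$truth, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(list(paths = paths, reference = ref, fusions = fus,
                 expression = expr, cohort = cohort))
}
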