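# Chimeric transcript construction, frame classification, spans, domains.

test_that("intronic breakpoints resolve to flanking exon boundaries; exonic pass through", {
  m <- anxa2_like_model()
  # intron-4 genomic breakpoint, 5' side -> last transcribed base of exon 4,
  # which on the minus strand is the exon's genomic start
  expect_equal(infer_mrna_breakpoint(m, 60656550, "5p"), 60656628)
  # 3' side -> first base of exon 5 in transcript orientation
  expect_equal(infer_mrna_breakpoint(m, 60656550, "3p"), 60656430)
  # exonic positions are cryptic junctions, returned unchanged (idempotent)
  expect_equal(infer_mrna_breakpoint(m, 60656650, "5p"), 60656650)
  expect_equal(infer_mrna_breakpoint(m, infer_mrna_breakpoint(m, 60656550, "5p"), "5p"),
               60656628)
  # a breakpoint at an exon's last transcribed base maps to itself
  expect_equal(infer_mrna_breakpoint(m, 60656628, "5p"), 60656628)
  expect_error(infer_mrna_breakpoint(m, 60650000, "5p"), "outside")
})

test_that("fused cDNA is the exact concatenation of the retained pieces", {
  fx <- make_fixture(
    make_coding_gene("F5", n_aa = 30, n_exons = 2, strand = "+", seed = 41),
    make_coding_gene("F3", n_aa = 30, n_exons = 2, strand = "-", seed = 42)
  )
  m5 <- fx$models[["F5.t1"]]
  m3 <- fx$models[["F3.t1"]]
  t5 <- 6L
  t3 <- 4L
  fused <- build_fusion_transcript(m5, transcript_to_genomic(m5, t5),
                                   m3, transcript_to_genomic(m3, t3),
                                   fx$genome)
  s5 <- transcript_sequence(m5, fx$genome)
  s3 <- transcript_sequence(m3, fx$genome)
  expect_identical(fused$junction, t5)
  expect_identical(nchar(fused$cdna), t5 + nchar(s3) - t3 + 1L)
  expect_identical(fused$cdna,
                   paste0(substr(s5, 1, t5), substr(s3, t3, nchar(s3))))
  # the minus-strand partner's spliced sequence is the reverse complement
  # of its genomically ordered exon sequence
  ex <- m3$exons
  plus_seq <- paste(substring(fx$genome$F3, ex$start, ex$end), collapse = "")
  expect_identical(s3, revcomp(plus_seq))
  expect_error(build_fusion_transcript(m5, m5$exons$end[1] + 1L, m3,
                                       transcript_to_genomic(m3, t3),
                                       fx$genome),
               "infer_mrna_breakpoint")
})

test_that("frame arithmetic reproduces the CLDN18-ARHGAP26 construct geometry", {
  # 5' partner retains coding bases 1-750, 3' partner restarts at CDS
  # offset 1108: 750 = 0 and 1107 = 0 (mod 3) -> in frame
  fx <- make_fixture(
    make_coding_gene("CLDN18L", n_aa = 261, n_exons = 4, seed = 51),
    make_coding_gene("ARHGAP26L", n_aa = 814, n_exons = 6, seed = 52)
  )
  m5 <- fx$models[["CLDN18L.t1"]]
  m3 <- fx$models[["ARHGAP26L.t1"]]
  g5 <- transcript_to_genomic(m5, m5$cds_start + 750L - 1L)
  g3 <- transcript_to_genomic(m3, m3$cds_start + 1108L - 1L)
  fr <- classify_frame(m5, g5, m3, g3, fx$genome)
  expect_identical(fr$status, "IN_FRAME")
  expect_identical(fr$n5_cds, 750L)
  expect_identical(fr$d3_offset, 1108L)
})

test_that("phase-zero and shifted junctions classify as the translation oracle dictates", {
  fx <- make_fixture(
    make_coding_gene("P5", n_aa = 50, n_exons = 3, seed = 61),
    make_coding_gene("P3", n_aa = 70, n_exons = 3, seed = 62)
  )
  m5 <- fx$models[["P5.t1"]]
  m3 <- fx$models[["P3.t1"]]
  # n5_cds = 3, d3_offset = 1: first residue of the 5' partner (Met) plus
  # the complete 3' protein
  g5 <- transcript_to_genomic(m5, m5$cds_start + 2L)
  g3 <- transcript_to_genomic(m3, m3$cds_start)
  fr <- classify_frame(m5, g5, m3, g3, fx$genome)
  expect_identical(fr$status, "IN_FRAME")
  fused <- build_fusion_transcript(m5, g5, m3, g3, fx$genome)
  tr <- translate_fusion(fused$cdna, fused$cds_start)
  expect_identical(tr$protein,
                   paste0("M", transcript_protein(m3, fx$genome)))
  # n5_cds = 100, d3_offset = 1: phases 1 vs 0 -> frameshift, and the
  # oracle agrees
  g5b <- transcript_to_genomic(m5, m5$cds_start + 99L)
  frb <- classify_frame(m5, g5b, m3, g3, fx$genome)
  expect_identical(frb$status, "FRAMESHIFT")
  expect_false(oracle_in_frame(m5, g5b, m3, g3, fx$genome))
})

test_that("promoter swap, non-coding and junction-stop cases are distinguished", {
  # handcrafted sequences so the junction codon is exactly TAA
  gA <- make_coding_gene("JA", cds_seq = "ATGTTTGCCTAA", utr5 = 9L,
                         utr3 = 12L, n_exons = 1L, seed = 71)
  gB <- make_coding_gene("JB", cds_seq = "ATGAAAGGCGGATGA", utr5 = 9L,
                         utr3 = 12L, n_exons = 1L, seed = 72)
  fx <- make_fixture(gA, gB)
  mA <- fx$models[["JA.t1"]]
  mB <- fx$models[["JB.t1"]]
  # t5 retains "ATGT" (n5 = 4, r = 1); d3 = 5 retains "AA..." -> hybrid
  # codon T + AA = TAA
  g5 <- transcript_to_genomic(mA, mA$cds_start + 3L)
  g3 <- transcript_to_genomic(mB, mB$cds_start + 4L)
  fr <- classify_frame(mA, g5, mB, g3, fx$genome)
  expect_identical(fr$status, "JUNCTION_STOP")
  expect_false(oracle_in_frame(mA, g5, mB, g3, fx$genome))

  # junction upstream of the 5' CDS with the whole 3' ORF retained
  g5u <- transcript_to_genomic(mA, 2L)
  g3u <- transcript_to_genomic(mB, mB$cds_start)
  expect_identical(classify_frame(mA, g5u, mB, g3u, fx$genome)$status,
                   "PROMOTER_SWAP")
  # ... but a truncated 3' CDS downstream of a non-coding 5' piece is dead
  g3t <- transcript_to_genomic(mB, mB$cds_start + 4L)
  expect_identical(classify_frame(mA, g5u, mB, g3t, fx$genome)$status,
                   "NON_CODING")
  # junction in the 5' partner's 3' UTR retains its native stop
  g5d <- transcript_to_genomic(mA, mA$cds_end + 2L)
  expect_identical(classify_frame(mA, g5d, mB, g3t, fx$genome)$status,
                   "NON_CODING")
})

test_that("translate_fusion implements the standard code with first-stop semantics", {
  tr <- translate_fusion("ATGGCCTAA", 1L)
  expect_identical(tr$protein, "MA")
  expect_true(tr$stopped)
  expect_identical(tr$stop_codon, 3L)
  expect_error(translate_fusion("ATG", 10L), "beyond")

  # in-frame fixture: the protein suffix equals the wild-type 3' suffix
  fx <- make_fixture(
    make_coding_gene("T5", n_aa = 40, n_exons = 2, seed = 81),
    make_coding_gene("T3", n_aa = 60, n_exons = 2, seed = 82)
  )
  m5 <- fx$models[["T5.t1"]]
  m3 <- fx$models[["T3.t1"]]
  g5 <- transcript_to_genomic(m5, m5$cds_start + 29L)  # n5 = 30
  g3 <- transcript_to_genomic(m3, m3$cds_start + 30L)  # d3 = 31
  expect_identical(classify_frame(m5, g5, m3, g3, fx$genome)$status, "IN_FRAME")
  fused <- build_fusion_transcript(m5, g5, m3, g3, fx$genome)
  tr2 <- translate_fusion(fused$cdna, fused$cds_start)
  p3 <- transcript_protein(m3, fx$genome)
  suffix <- substr(p3, 11L, nchar(p3))  # d3 = 31 -> first native codon 11
  expect_identical(substr(tr2$protein, nchar(tr2$protein) - nchar(suffix) + 1L,
                          nchar(tr2$protein)),
                   suffix)
})

test_that("retained spans follow the printed aa-span arithmetic", {
  fr <- list(status = "IN_FRAME", n5_cds = 144L, d3_offset = 58L)
  sp <- retained_spans(fr, protein3_length = 271L)
  expect_identical(sp$aa5_span, c(1L, 48L))     # 144 nt = 48 codons
  expect_identical(sp$aa3_span, c(20L, 271L))   # offset 58 -> residue 20
  expect_false(sp$has_junction_residue)         # 144 = 0 mod 3

  sp0 <- retained_spans(list(status = "IN_FRAME", n5_cds = 0L,
                             d3_offset = 1L), 100L)
  expect_null(sp0$aa5_span)
  expect_error(retained_spans(list(status = "FRAMESHIFT", n5_cds = 10L,
                                   d3_offset = 1L), 100L),
               "IN_FRAME")
})

test_that("domain retention requires full containment and drives class labels", {
  domains <- data.frame(
    gene_name = c("MYO9AL", "MYO9AL", "PPAPDC1AL", "CTNND1L"),
    domain_name = c("RhoGAP", "C1", "PAP2", "Arm"),
    aa_start = c(2120, 1850, 80, 50),
    aa_end = c(2320, 2050, 210, 450),
    stringsAsFactors = FALSE
  )
  res <- retained_domains(NULL, c(1994L, 2548L), domains, "ANXA2L", "MYO9AL")
  expect_setequal(res$retained$domain_name, "RhoGAP")
  expect_identical(res$truncated$domain_name, "C1")  # 1850 < 1994: clipped
  expect_identical(res$class_labels, "RhoGAP-domain fusion")

  res2 <- retained_domains(c(1L, 48L), c(20L, 271L), domains,
                           "TACC2L", "PPAPDC1AL")
  expect_identical(res2$class_labels, "PAP2-domain fusion")

  empty <- retained_domains(c(1L, 100L), c(1L, 100L),
                            domains[0, ], "A", "B")
  expect_identical(nrow(empty$retained), 0L)
  expect_identical(empty$class_labels, character(0))

  # monotonicity: enlarging a retained span never loses a domain
  set.seed(9)
  for (i in 1:25) {
    a <- sample(1:200, 1)
    b <- a + sample(0:300, 1)
    r1 <- retained_domains(NULL, c(a, b), domains, "x", "MYO9AL")$retained
    r2 <- retained_domains(NULL, c(max(1, a - 10), b + 25), domains,
                           "x", "MYO9AL")$retained
    expect_true(all(r1$domain_name %in% r2$domain_name))
  }
})

test_that("annotate_candidate composes the stages and enforces oracle consistency", {
  cfg <- sim_config(seed = 13, n_samples = 20,
                    fusions = data.frame(
                      gene5 = c("G01", "G03"), gene3 = c("G02", "G04"),
                      n_carriers = c(2L, 2L),
                      breakpoint_type = c("intronic", "exonic"),
                      truth_frame = c("in_frame", "frameshift"),
                      stringsAsFactors = FALSE))
  ref <- simulate_reference(cfg)
  fus <- simulate_fusions(cfg, ref)
  anns <- lapply(seq_len(nrow(fus$candidates)), function(i) {
    annotate_candidate(fus$candidates[i, ], ref$models, ref$domains,
                       ref$genome)
  })
  status <- vapply(anns, `[[`, "", "frame_status")
  expect_identical(unname(status[fus$candidates$truth == "in_frame"]),
                   rep("IN_FRAME", sum(fus$candidates$truth == "in_frame")))
  expect_identical(unname(status[fus$candidates$truth == "frameshift"]),
                   rep("FRAMESHIFT", sum(fus$candidates$truth == "frameshift")))
  # class labels agree with the span/domain geometry of the inputs
  inside <- function(gene, span, name) {
    d <- ref$domains[ref$domains$gene_name == gene &
                       ref$domains$domain_name == name, ]
    nrow(d) > 0 && !is.null(span) &&
      any(d$aa_start >= span[1] & d$aa_end <= span[2])
  }
  for (a in anns) {
    if (a$frame_status != "IN_FRAME") next
    rhogap_expected <- inside(a$gene5, a$aa5_span, "RhoGAP") ||
      inside(a$gene3, a$aa3_span, "RhoGAP")
    expect_identical("RhoGAP-domain fusion" %in% a$class_labels,
                     rhogap_expected)
  }

  cand <- fus$candidates[1, ]
  cand$gene3 <- cand$gene5
  cand$pos3 <- cand$pos5 + 1
  expect_error(annotate_candidate(cand, ref$models, ref$domains, ref$genome),
               "degenerate")
  cand2 <- fus$candidates[1, ]
  cand2$gene3 <- "NOT_A_GENE"
  expect_error(annotate_candidate(cand2, ref$models, ref$domains, ref$genome),
               "NOT_A_GENE")
})

test_that("in-frame fusion protein length follows the span decomposition", {
  fx <- make_fixture(
    make_coding_gene("L5", n_aa = 80, n_exons = 3, seed = 91),
    make_coding_gene("L3", n_aa = 90, n_exons = 3, seed = 92)
  )
  m5 <- fx$models[["L5.t1"]]
  m3 <- fx$models[["L3.t1"]]
  p3_len <- nchar(transcript_protein(m3, fx$genome))
  set.seed(17)
  checked <- 0
  while (checked < 20) {
    t5 <- sample(seq(m5$cds_start, m5$cds_end - 4L), 1)
    t3 <- sample(seq(m3$cds_start, m3$cds_end - 6L), 1)
    g5 <- transcript_to_genomic(m5, t5)
    g3 <- transcript_to_genomic(m3, t3)
    fr <- classify_frame(m5, g5, m3, g3, fx$genome)
    if (fr$status != "IN_FRAME") next
    checked <- checked + 1
    sp <- retained_spans(fr, p3_len)
    fused <- build_fusion_transcript(m5, g5, m3, g3, fx$genome)
    prot <- translate_fusion(fused$cdna, fused$cds_start)$protein
    n5_aa <- if (is.null(sp$aa5_span)) 0L else sp$aa5_span[2L]
    n3_aa <- if (is.null(sp$aa3_span)) 0L else sp$aa3_span[2L] - sp$aa3_span[1L] + 1L
    expect_identical(nchar(prot),
                     n5_aa + n3_aa + as.integer(sp$has_junction_residue))
  }
})
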