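# Fixture builders shared across the test files. Everything is generated
# in code; no binary or downloaded data.

BASES <- c("A", "C", "G", "T")
SENSE_CODONS <- local({
  all <- as.vector(outer(outer(BASES, BASES, paste0), BASES, paste0))
  setdiff(all, c("TAA", "TAG", "TGA"))
})

rand_dna <- function(n) paste(sample(BASES, n, replace = TRUE), collapse = "")

revcomp <- function(s) {
  chartr("ACGT", "TGCA", paste(rev(strsplit(s, "")[[1]]), collapse = ""))
}

# A coding gene with an explicit (or random) spliced sequence, split into
# exons with introns, placed on its own contig. Returns the transcript
# model plus the contig sequence (named by `contig`).
make_coding_gene <- function(gene, n_aa = NULL, utr5 = 30L, utr3 = 30L,
                             n_exons = 3L, strand = "+", contig = gene,
                             offset = 100L, intron_len = 60L,
                             cds_seq = NULL, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(cds_seq)) {
    cds_seq <- paste0("ATG",
                      paste(sample(SENSE_CODONS, n_aa - 1L, replace = TRUE),
                            collapse = ""),
                      "TAA")
  }
  spliced <- paste0(rand_dna(utr5), cds_seq, rand_dna(utr3))
  tlen <- nchar(spliced)
  # split tlen into n_exons parts of >= 10 nt
  cuts <- sort(sample(seq(10L, tlen - 10L), n_exons - 1L))
  while (any(diff(c(0L, cuts, tlen)) < 10L)) {
    cuts <- sort(sample(seq(10L, tlen - 10L), n_exons - 1L))
  }
  ex_len <- diff(c(0L, cuts, tlen))
  ex_start_t <- cumsum(c(1L, ex_len))[seq_len(n_exons)]
  ex_seq <- substring(spliced, ex_start_t, ex_start_t + ex_len - 1L)
  introns <- vapply(seq_len(n_exons - 1L), function(i) rand_dna(intron_len), "")
  premrna <- character(2L * n_exons - 1L)
  premrna[seq(1L, length(premrna), by = 2L)] <- ex_seq
  if (n_exons > 1L) premrna[seq(2L, length(premrna) - 1L, by = 2L)] <- introns
  gseq <- paste(premrna, collapse = "")
  glen <- nchar(gseq)
  piece_len <- integer(0)
  for (i in seq_len(n_exons)) {
    piece_len <- c(piece_len, ex_len[i],
                   if (i < n_exons) intron_len else NULL)
  }
  piece_end <- cumsum(piece_len)
  ex_b <- piece_end[seq(1L, length(piece_len), by = 2L)]
  ex_a <- ex_b - ex_len + 1L
  if (strand == "+") {
    exons <- data.frame(start = offset + ex_a - 1L, end = offset + ex_b - 1L)
    contig_seq <- paste0(rand_dna(offset - 1L), gseq)
  } else {
    exons <- data.frame(start = offset + glen - ex_b, end = offset + glen - ex_a)
    contig_seq <- paste0(rand_dna(offset - 1L), revcomp(gseq))
  }
  model <- transcript_model(
    gene_id = gene, gene_name = gene, transcript_id = paste0(gene, ".t1"),
    contig = contig, strand = strand, exons = exons,
    cds_start = utr5 + 1L, cds_end = utr5 + nchar(cds_seq)
  )
  list(model = model, seq = setNames(contig_seq, contig))
}

# Assemble make_coding_gene() outputs into a genome + model list.
make_fixture <- function(...) {
  genes <- list(...)
  genome <- structure(
    lapply(genes, function(g) unname(g$seq)), class = "genome_sequence"
  )
  names(genome) <- vapply(genes, function(g) names(g$seq), "")
  models <- lapply(genes, `[[`, "model")
  names(models) <- vapply(models, `[[`, "", "transcript_id")
  list(genome = genome, models = models)
}

# Coordinate-only transcript model (no backing sequence needed).
make_model <- function(gene, contig, strand, exons, cds_start = NA,
                       cds_end = NA) {
  transcript_model(gene_id = gene, gene_name = gene,
                   transcript_id = paste0(gene, ".t1"), contig = contig,
                   strand = strand, exons = exons,
                   cds_start = cds_start, cds_end = cds_end)
}

# Minus-strand model shaped like the ANXA2 locus: exon 4 (transcript
# orientation) starts genomically at 60,656,628, and intron 4 lies
# genomically below it, containing 60,656,550. Exon extents other than
# that boundary are invented.
anxa2_like_model <- function() {
  make_model(
    "ANXA2L", "chr15", "-",
    data.frame(
      start = c(60656100, 60656350, 60656628, 60656900, 60657200, 60657500),
      end   = c(60656220, 60656430, 60656720, 60657010, 60657320, 60657640)
    )
  )
}

# Independent translation-based in-frame decision used as the oracle in
# frame-classifier tests: translate the fused cDNA with Biostrings and
# require termination exactly at the native 3'-partner stop plus exact
# recovery of the native 3' protein suffix.
oracle_in_frame <- function(m5, g5, m3, g3, genome) {
  fused <- build_fusion_transcript(m5, g5, m3, g3, genome)
  if (is.na(fused$cds_start)) return(FALSE)
  orf <- substr(fused$cdna, fused$cds_start, nchar(fused$cdna))
  orf <- substr(orf, 1L, (nchar(orf) %/% 3L) * 3L)
  if (nchar(orf) < 3L) return(FALSE)
  aa <- suppressWarnings(as.character(
    Biostrings::translate(Biostrings::DNAString(orf), no.init.codon = TRUE)
  ))
  stop_i <- regexpr("*", aa, fixed = TRUE)
  rem <- m3$cds_end - fused$t3 + 1L
  l_tot <- (fused$junction - fused$cds_start + 1L) + rem
  if (rem < 3L || l_tot %% 3L != 0L || stop_i != l_tot %/% 3L) return(FALSE)
  p3 <- transcript_protein(m3, genome)
  d3 <- max(1L, fused$t3 - m3$cds_start + 1L)
  b <- ceiling((d3 + 2L) / 3L)
  if (b > nchar(p3)) return(TRUE)
  suf <- substr(p3, b, nchar(p3))
  prot <- substr(aa, 1L, stop_i - 1L)
  nchar(prot) >= nchar(suf) &&
    substr(prot, nchar(prot) - nchar(suf) + 1L, nchar(prot)) == suf
}
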