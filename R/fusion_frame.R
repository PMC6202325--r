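# Chimeric transcript construction and reading-frame classification.
#
# Breakpoint semantics (mirrored in every function below): the 5'-partner
# coordinate is the LAST transcribed base retained from the 5' gene; the
# 3'-partner coordinate is the FIRST base retained from the 3' gene.  DNA
# (genomic) breakpoints falling in introns are first resolved to the
# flanking exon boundary by infer_mrna_breakpoint(), emulating splicing of
# the rearranged allele; exonic DNA breakpoints are treated as cryptic
# junctions and used as-is.

FRAME_STATUSES <- c("IN_FRAME", "FRAMESHIFT", "PROMOTER_SWAP",
                    "NON_CODING", "JUNCTION_STOP")

#' Resolve a genomic breakpoint to its mRNA-level breakpoint
#'
#' An intronic genomic breakpoint is spliced out of the mature chimeric
#' transcript, so the observed mRNA breakpoint is the flanking exon
#' boundary: for the 5' partner the last base of the exon preceding the
#' intron (in transcript orientation), for the 3' partner the first base of
#' the exon following it. Exonic positions (cryptic junctions) are returned
#' unchanged; the operation is therefore idempotent.
#'
#' @param model A [transcript_model()].
#' @param gpos Genomic breakpoint position.
#' @param side `"5p"` if `model` is the 5' fusion partner, `"3p"` otherwise.
#' @return Genomic position of the predicted mRNA breakpoint.
#' @export
infer_mrna_breakpoint <- function(model, gpos, side = c("5p", "3p")) {
  side <- match.arg(side)
  hit <- genomic_to_transcript(model, gpos)
  if (hit$kind == "outside") {
    ff_stop(sprintf("breakpoint %s outside the span of transcript %s",
                    format(gpos, big.mark = ","), model$transcript_id))
  }
  if (hit$kind == "exonic") return(gpos)
  ex <- exons_in_transcript_order(model)
  i <- hit$intron
  if (side == "5p") {
    # last transcribed base of exon i
    if (model$strand == "+") ex$end[i] else ex$start[i]
  } else {
    # first transcribed base of exon i + 1
    if (model$strand == "+") ex$start[i + 1L] else ex$end[i + 1L]
  }
}

#' Spliced transcript sequence
#'
#' Concatenates the exon sequences of a model in transcript orientation,
#' reverse-complementing for minus-strand transcripts.
#'
#' @param model A `transcript_model`.
#' @param genome A `genome_sequence`.
#' @return Single uppercase string of length `transcript_length(model)`.
#' @export
transcript_sequence <- function(model, genome) {
  contig_seq <- genome[[model$contig]]
  if (is.null(contig_seq)) {
    ff_stop(paste0("contig not in genome: ", model$contig))
  }
  ex <- model$exons
  pieces <- substring(contig_seq, ex$start, ex$end)
  s <- paste(pieces, collapse = "")
  if (model$strand == "-") {
    s <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
  }
  s
}

#' Build the fused cDNA of a chimeric transcript
#'
#' Joins the 5' partner transcript up to (and including) the mRNA
#' breakpoint with the 3' partner transcript from its breakpoint to the
#' transcript end.
#'
#' @param model5,model3 Transcript models of the 5' and 3' partners.
#' @param bp5,bp3 mRNA-level (exonic) genomic breakpoints: last retained
#'   base of the 5' partner, first retained base of the 3' partner.
#' @param genome A `genome_sequence`.
#' @return A list: `cdna` (fused sequence), `junction` (transcript position
#'   of the last 5'-partner base within the fusion), `t5`, `t3` (breakpoint
#'   transcript coordinates in the native transcripts), and `cds_start`
#'   (transcript coordinate of the retained translation start, `NA` when
#'   the 5' CDS start is not retained).
#' @export
build_fusion_transcript <- function(model5, bp5, model3, bp3, genome) {
  t5 <- breakpoint_tpos(model5, bp5)
  t3 <- breakpoint_tpos(model3, bp3)
  seq5 <- transcript_sequence(model5, genome)
  seq3 <- transcript_sequence(model3, genome)
  cdna <- paste0(substr(seq5, 1L, t5), substr(seq3, t3, nchar(seq3)))
  cds_start <- if (model5$coding && t5 >= model5$cds_start) {
    model5$cds_start
  } else {
    NA_integer_
  }
  list(cdna = cdna, junction = t5, t5 = t5, t3 = t3, cds_start = cds_start)
}

breakpoint_tpos <- function(model, gpos) {
  hit <- genomic_to_transcript(model, gpos)
  if (hit$kind != "exonic") {
    ff_stop(sprintf(
      "breakpoint %s is not exonic in %s (%s); resolve it with infer_mrna_breakpoint() first",
      format(gpos, big.mark = ","), model$transcript_id, hit$kind
    ))
  }
  hit$tpos
}

#' Classify the reading frame of a chimeric transcript
#'
#' From the two mRNA breakpoints the number of retained 5'-partner coding
#' bases (`n5_cds`) and the 1-based offset of the first retained base
#' within the 3' CDS (`d3_offset`) are computed; the fusion is in frame
#' when the retained 5' coding length and the 3' entry offset agree in
#' phase: `n5_cds mod 3 == (d3_offset - 1) mod 3`.
#'
#' CDS transcript coordinates in this package *include* the terminal stop
#' codon, so a junction at or past `cds_end5` retains a complete native 5'
#' stop (translation cannot cross into the 3' partner) and a 3' breakpoint
#' inside its stop codon destroys the native terminator; both are
#' classified `NON_CODING`.
#'
#' Classification:
#' * `PROMOTER_SWAP` — junction upstream of the 5' CDS start while the 3'
#'   CDS is fully retained (the intact 3' ORF is driven by the 5' promoter);
#' * `NON_CODING` — no retained translation start, a fully retained native
#'   5' stop, or a lost/broken 3' stop codon;
#' * `IN_FRAME` — phases agree and no stop codon arises at the junction;
#' * `JUNCTION_STOP` — phases agree but a stop codon is created at the
#'   junction (in the hybrid codon, or within retained 3'-partner
#'   5'-UTR sequence read through before the native 3' start);
#' * `FRAMESHIFT` — phases disagree.
#'
#' @param model5,model3 Coding transcript models of the two partners.
#' @param bp5,bp3 mRNA-level (exonic) genomic breakpoints.
#' @param genome A `genome_sequence` (needed to inspect junction codons).
#' @return List with `status`, `n5_cds`, `d3_offset` (`0` denotes a 3'
#'   breakpoint upstream of the 3' CDS, i.e. the full 3' ORF is retained),
#'   `t5`, `t3`.
#' @export
classify_frame <- function(model5, bp5, model3, bp3, genome) {
  if (!model5$coding || !model3$coding) {
    ff_stop("classify_frame requires coding transcript models on both sides")
  }
  t5 <- breakpoint_tpos(model5, bp5)
  t3 <- breakpoint_tpos(model3, bp3)
  n5_cds <- max(0L, min(t5, model5$cds_end) - model5$cds_start + 1L)
  d3_offset <- if (t3 < model3$cds_start) 0L else t3 - model3$cds_start + 1L
  res <- list(status = NA_character_, n5_cds = n5_cds, d3_offset = d3_offset,
              t5 = t5, t3 = t3)
  if (t5 < model5$cds_start) {
    # no retained translation start from the 5' partner
    res$status <- if (t3 <= model3$cds_start) "PROMOTER_SWAP" else "NON_CODING"
    return(res)
  }
  if (t5 >= model5$cds_end) {
    # complete native 5' stop codon retained: translation never crosses
    res$status <- "NON_CODING"
    return(res)
  }
  if (t3 > model3$cds_end - 2L) {
    # native 3' stop codon lost or broken
    res$status <- "NON_CODING"
    return(res)
  }
  if (d3_offset == 0L) {
    # junction upstream of the 3' CDS: the retained 5'-UTR spacer of the 3'
    # partner is read through, so the 3' ORF stays in frame iff the spacer
    # plus the retained 5' coding bases fill whole codons
    u <- model3$cds_start - t3
    if ((n5_cds + u) %% 3L != 0L) {
      res$status <- "FRAMESHIFT"
      return(res)
    }
    res$status <- if (junction_region_has_stop(model5, model3, t5, t3, genome)) {
      "JUNCTION_STOP"
    } else {
      "IN_FRAME"
    }
    return(res)
  }
  phase5 <- n5_cds %% 3L
  phase3 <- (d3_offset - 1L) %% 3L
  if (phase5 != phase3) {
    res$status <- "FRAMESHIFT"
    return(res)
  }
  res$status <- if (phase5 != 0L &&
                    junction_codon_is_stop(model5, model3, t5, t3, n5_cds,
                                           genome)) {
    "JUNCTION_STOP"
  } else {
    "IN_FRAME"
  }
  res
}

STOP_CODONS <- c("TAA", "TAG", "TGA")

# The hybrid codon takes its first (n5_cds mod 3) bases from the 5' partner
# and the remainder from the 3' partner.
junction_codon_is_stop <- function(model5, model3, t5, t3, n5_cds, genome) {
  r <- n5_cds %% 3L
  seq5 <- transcript_sequence(model5, genome)
  seq3 <- transcript_sequence(model3, genome)
  part5 <- substr(seq5, t5 - r + 1L, t5)
  part3 <- substr(seq3, t3, t3 + (3L - r) - 1L)
  codon <- paste0(part5, part3)
  nchar(codon) == 3L && codon %in% STOP_CODONS
}

# Stop scan over the codon-aligned stretch running from the retained 5' CDS
# through the retained 3'-partner 5'-UTR spacer up to the native 3' start.
junction_region_has_stop <- function(model5, model3, t5, t3, genome) {
  seq5 <- transcript_sequence(model5, genome)
  seq3 <- transcript_sequence(model3, genome)
  prefix <- paste0(substr(seq5, model5$cds_start, t5),
                   substr(seq3, t3, model3$cds_start - 1L))
  starts <- seq.int(1L, nchar(prefix), by = 3L)
  codons <- substring(prefix, starts, starts + 2L)
  any(codons %in% STOP_CODONS)
}

#' Translate a fused cDNA
#'
#' Standard-genetic-code translation from the fused CDS start to the first
#' stop codon or the end of the sequence. Incomplete trailing codons are
#' dropped.
#'
#' @param cdna Fused cDNA string.
#' @param cds_start 1-based position of the first coding base.
#' @return List with `protein` (amino-acid string, stop excluded), `stopped`
#'   (was a stop codon reached), and `stop_codon` (codon index of the stop,
#'   `NA` if none).
#' @export
translate_fusion <- function(cdna, cds_start) {
  if (is.na(cds_start) || cds_start < 1L || cds_start > nchar(cdna)) {
    ff_stop("translate_fusion: CDS start undefined or beyond the sequence")
  }
  s <- substr(cdna, cds_start, nchar(cdna))
  n_codon <- nchar(s) %/% 3L
  if (n_codon == 0L) return(list(protein = "", stopped = FALSE, stop_codon = NA_integer_))
  starts <- seq.int(1L, by = 3L, length.out = n_codon)
  codons <- substring(s, starts, starts + 2L)
  aa <- unname(Biostrings::GENETIC_CODE[codons])
  aa[is.na(aa)] <- "X"  # codons containing N
  stop_at <- which(aa == "*")[1L]
  if (!is.na(stop_at)) {
    list(protein = paste(aa[seq_len(stop_at - 1L)], collapse = ""),
         stopped = TRUE, stop_codon = stop_at)
  } else {
    list(protein = paste(aa, collapse = ""), stopped = FALSE,
         stop_codon = NA_integer_)
  }
}

#' Protein sequence of a transcript model
#' @param model Coding `transcript_model`.
#' @param genome A `genome_sequence`.
#' @return Amino-acid string (terminal stop excluded).
#' @export
transcript_protein <- function(model, genome) {
  if (!model$coding) ff_stop("transcript_protein: non-coding model")
  translate_fusion(transcript_sequence(model, genome), model$cds_start)$protein
}

#' Retained amino-acid spans of an in-frame fusion
#'
#' The 5' partner retains amino acids `[1, floor(n5_cds / 3)]`; the 3'
#' partner retains from its first fully native codon at or after the entry
#' offset through the end of its protein. When the junction is not
#' codon-aligned the hybrid junction residue belongs to neither span and is
#' reported separately.
#'
#' @param frame Result of [classify_frame()] with status `IN_FRAME` (or
#'   `JUNCTION_STOP`, for inspection).
#' @param protein3_length Length (aa) of the native 3'-partner protein.
#' @return List with `aa5_span`, `aa3_span` (integer length-2 vectors;
#'   `NULL` when empty) and `has_junction_residue`.
#' @export
retained_spans <- function(frame, protein3_length) {
  if (!frame$status %in% c("IN_FRAME", "JUNCTION_STOP")) {
    ff_stop("retained_spans: frame status is not IN_FRAME")
  }
  a <- frame$n5_cds %/% 3L
  aa5 <- if (a >= 1L) c(1L, a) else NULL
  b <- as.integer(ceiling((frame$d3_offset + 2L) / 3L))
  aa3 <- if (b <= protein3_length) c(b, as.integer(protein3_length)) else NULL
  list(aa5_span = aa5, aa3_span = aa3,
       has_junction_residue = frame$n5_cds %% 3L != 0L)
}

#' Retained protein domains and fusion class labels
#'
#' A domain is *retained* only if its full protein interval lies inside the
#' retained span of its partner; a domain merely overlapping the span is
#' reported as truncated. Class labels follow the retained domains:
#' a fusion retaining a RhoGAP domain (either side) is a "RhoGAP-domain
#' fusion", one retaining a PAP2 domain a "PAP2-domain fusion".
#'
#' @param aa5_span,aa3_span Retained spans from [retained_spans()] (`NULL`
#'   when empty).
#' @param domains Domain data frame ([load_domain_table()]).
#' @param gene5,gene3 Gene names of the two partners.
#' @return List with `retained` (data.frame gene_name/domain_name/side),
#'   `truncated` (same shape) and `class_labels` (character vector).
#' @export
retained_domains <- function(aa5_span, aa3_span, domains, gene5, gene3) {
  empty <- data.frame(gene_name = character(), domain_name = character(),
                      side = character(), stringsAsFactors = FALSE)
  retained <- empty
  truncated <- empty
  check_side <- function(gene, span, side) {
    d <- domains[domains$gene_name == gene, , drop = FALSE]
    if (nrow(d) == 0L || is.null(span)) return()
    inside <- d$aa_start >= span[1L] & d$aa_end <= span[2L]
    overlap <- d$aa_start <= span[2L] & d$aa_end >= span[1L]
    if (any(inside)) {
      retained <<- rbind(retained, data.frame(
        gene_name = gene, domain_name = d$domain_name[inside], side = side,
        stringsAsFactors = FALSE
      ))
    }
    part <- overlap & !inside
    if (any(part)) {
      truncated <<- rbind(truncated, data.frame(
        gene_name = gene, domain_name = d$domain_name[part], side = side,
        stringsAsFactors = FALSE
      ))
    }
  }
  check_side(gene5, aa5_span, "5p")
  check_side(gene3, aa3_span, "3p")
  labels <- character()
  if (any(retained$domain_name == "RhoGAP")) labels <- c(labels, "RhoGAP-domain fusion")
  if (any(retained$domain_name == "PAP2")) labels <- c(labels, "PAP2-domain fusion")
  list(retained = retained, truncated = truncated, class_labels = labels)
}

#' Annotate one fusion candidate end to end
#'
#' Composes breakpoint resolution, fused-transcript construction, frame
#' classification, translation, retained spans and retained domains into a
#' single annotation. The arithmetic frame call is always cross-checked
#' against the translation of the actual fused cDNA (no premature stop and
#' exact recovery of the native 3'-partner protein suffix); an internal
#' inconsistency raises an error rather than returning a wrong label.
#'
#' @param candidate A list or one-row data frame with fields `sample_id`,
#'   `gene5`, `contig5`, `pos5`, `gene3`, `contig3`, `pos3`, `provenance`
#'   (`"mrna"` or `"genomic"`).
#' @param models Named list of transcript models; gene names are resolved
#'   to their canonical transcript via [select_canonical()].
#' @param domains Domain table data frame.
#' @param genome A `genome_sequence`.
#' @return An object of class `fusion_annotation`: a list with the frame
#'   result, fused protein, retained spans, retained domains and class
#'   labels.
#' @export
annotate_candidate <- function(candidate, models, domains, genome) {
  cand <- as.list(candidate)
  model5 <- canonical_for_gene(models, cand$gene5)
  model3 <- canonical_for_gene(models, cand$gene3)
  if (identical(cand$gene5, cand$gene3) &&
      abs(as.numeric(cand$pos5) - as.numeric(cand$pos3)) <= 1) {
    ff_stop("degenerate candidate: identical partners with adjacent breakpoints")
  }
  provenance <- if (is.null(cand$provenance)) "genomic" else cand$provenance
  bp5 <- as.numeric(cand$pos5)
  bp3 <- as.numeric(cand$pos3)
  if (provenance == "genomic") {
    bp5 <- infer_mrna_breakpoint(model5, bp5, "5p")
    bp3 <- infer_mrna_breakpoint(model3, bp3, "3p")
  }
  frame <- classify_frame(model5, bp5, model3, bp3, genome)
  fused <- build_fusion_transcript(model5, bp5, model3, bp3, genome)

  protein3 <- transcript_protein(model3, genome)
  translation <- if (!is.na(fused$cds_start)) {
    translate_fusion(fused$cdna, fused$cds_start)
  } else {
    NULL
  }
  oracle_in_frame <- frame_oracle(fused, model3, protein3, genome)
  arithmetic_in_frame <- frame$status == "IN_FRAME"
  if (arithmetic_in_frame != oracle_in_frame) {
    ff_stop(sprintf(
      "internal consistency failure for %s-%s: frame arithmetic says %s but the translation oracle disagrees",
      cand$gene5, cand$gene3, frame$status
    ))
  }

  spans <- if (frame$status == "IN_FRAME") {
    retained_spans(frame, nchar(protein3))
  } else {
    list(aa5_span = NULL, aa3_span = NULL, has_junction_residue = FALSE)
  }
  doms <- retained_domains(spans$aa5_span, spans$aa3_span, domains,
                           cand$gene5, cand$gene3)
  structure(list(
    sample_id = cand$sample_id, gene5 = cand$gene5, gene3 = cand$gene3,
    mrna_bp5 = bp5, mrna_bp3 = bp3, provenance = provenance,
    frame_status = frame$status, n5_cds = frame$n5_cds,
    d3_offset = frame$d3_offset,
    aa5_span = spans$aa5_span, aa3_span = spans$aa3_span,
    has_junction_residue = spans$has_junction_residue,
    fusion_protein = if (!is.null(translation)) translation$protein else NA_character_,
    retained_domains = doms$retained, truncated_domains = doms$truncated,
    class_labels = doms$class_labels
  ), class = "fusion_annotation")
}

canonical_for_gene <- function(models, gene) {
  hits <- Filter(function(m) m$gene_name == gene || m$gene_id == gene, models)
  if (length(hits) == 0L) {
    ff_stop(paste0("gene not present in the transcript models: ", gene))
  }
  select_canonical(hits)
}

# Brute-force decision used as the internal oracle: the fusion is in frame
# iff translating the fused cDNA from the retained start terminates exactly
# at the native 3'-partner stop codon and recovers, without a premature
# stop, exactly the native 3'-partner protein suffix downstream of the
# junction. Purely string-based; shares no arithmetic with classify_frame.
frame_oracle <- function(fused, model3, protein3, genome) {
  if (is.na(fused$cds_start)) return(FALSE)
  cds3_remaining <- model3$cds_end - fused$t3 + 1L
  if (cds3_remaining < 3L) return(FALSE)  # 3' stop codon lost or broken
  # total ORF span if translation were to run from the retained start to the
  # native 3' stop: must fill whole codons for the stop to be in frame
  orf_len <- (fused$junction - fused$cds_start + 1L) + cds3_remaining
  if (orf_len %% 3L != 0L) return(FALSE)
  tr <- translate_fusion(fused$cdna, fused$cds_start)
  if (!tr$stopped || tr$stop_codon != orf_len %/% 3L) return(FALSE)
  # the translated suffix must equal the native 3' protein suffix
  d3 <- max(1L, fused$t3 - model3$cds_start + 1L)
  b <- as.integer(ceiling((d3 + 2L) / 3L))
  if (b > nchar(protein3)) return(TRUE)  # no complete native residue retained
  suffix3 <- substr(protein3, b, nchar(protein3))
  nchar(tr$protein) >= nchar(suffix3) &&
    substr(tr$protein, nchar(tr$protein) - nchar(suffix3) + 1L,
           nchar(tr$protein)) == suffix3
}

#' @export
print.fusion_annotation <- function(x, ...) {
  span_str <- function(s) if (is.null(s)) "-" else paste0(s[1], "-", s[2])
  cat(sprintf(
    "<fusion_annotation> %s-%s [%s]\n  mRNA breakpoints %s | %s\n  aa spans 5':%s 3':%s%s\n",
    x$gene5, x$gene3, x$frame_status,
    format(x$mrna_bp5, big.mark = ","), format(x$mrna_bp3, big.mark = ","),
    span_str(x$aa5_span), span_str(x$aa3_span),
    if (length(x$class_labels)) paste0("\n  ", paste(x$class_labels, collapse = ", ")) else ""
  ))
  invisible(x)
}
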