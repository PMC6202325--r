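# Reference annotation: genome sequences, transcript models, protein domains,
# and genomic <-> transcript coordinate mapping.
#
# Coordinate conventions used throughout the package:
#   * genomic positions are 1-based and inclusive;
#   * transcript coordinate 1 is the first transcribed base, so on the minus
#     strand it is the genomically 3'-most base of the transcript span;
#   * introns are numbered in transcript orientation (intron i follows exon i).

#' Load a reference genome from FASTA
#'
#' Reads a (possibly line-wrapped) multi-record FASTA file into a named list
#' of uppercase nucleotide strings, one per contig.
#'
#' @param path Path to a FASTA file.
#' @return An object of class `genome_sequence`: a named list of single
#'   uppercase strings over the alphabet A/C/G/T/N, names are contig names.
#' @export
load_genome <- function(path) {
  if (!file.exists(path)) ff_format_error(paste0("FASTA file not found: ", path))
  set <- Biostrings::readDNAStringSet(path)
  if (length(set) == 0L) ff_format_error("FASTA file contains no records")
  nm <- sub("\\s.*$", "", names(set))
  if (anyDuplicated(nm)) {
    ff_format_error(paste0(
      "duplicate contig name in FASTA: ",
      paste(unique(nm[duplicated(nm)]), collapse = ", ")
    ))
  }
  if (any(Biostrings::width(set) == 0L)) ff_format_error("empty FASTA record")
  seqs <- toupper(as.character(set))
  if (any(grepl("[^ACGTN]", seqs))) {
    ff_format_error("FASTA sequence contains characters outside A/C/G/T/N")
  }
  structure(as.list(setNames(seqs, nm)), class = "genome_sequence")
}

#' Write a genome to FASTA
#'
#' @param genome A `genome_sequence` object.
#' @param path Output path.
#' @param width Line-wrap width.
#' @return `path`, invisibly.
#' @export
write_genome <- function(genome, path, width = 70L) {
  set <- Biostrings::DNAStringSet(unlist(genome))
  names(set) <- names(genome)
  Biostrings::writeXStringSet(set, path, width = width)
  invisible(path)
}

#' Construct a transcript model
#'
#' A transcript model is the coordinate backbone for all breakpoint
#' arithmetic: the ordered exon structure of one transcript on a strand,
#' plus the CDS expressed in transcript coordinates.
#'
#' @param gene_id,gene_name,transcript_id Identifiers.
#' @param contig Contig name.
#' @param strand `"+"` or `"-"`.
#' @param exons Data frame with columns `start`, `end` (1-based inclusive
#'   genomic intervals); may be unsorted, will be sorted by genomic start.
#' @param cds_start,cds_end First and last coding base in *transcript*
#'   coordinates, or `NA` for a non-coding transcript.
#' @return An object of class `transcript_model`.
#' @export
transcript_model <- function(gene_id, gene_name, transcript_id, contig, strand,
                             exons, cds_start = NA_integer_, cds_end = NA_integer_) {
  stopifnot(strand %in% c("+", "-"))
  exons <- as.data.frame(exons)[, c("start", "end")]
  exons <- exons[order(exons$start), , drop = FALSE]
  rownames(exons) <- NULL
  if (any(exons$end < exons$start)) ff_format_error("exon with end < start")
  if (nrow(exons) > 1L && any(exons$start[-1L] <= exons$end[-nrow(exons)])) {
    ff_format_error(paste0("overlapping exons in transcript ", transcript_id))
  }
  len <- sum(exons$end - exons$start + 1L)
  coding <- !is.na(cds_start) && !is.na(cds_end)
  if (coding) {
    if (!(cds_start >= 1L && cds_start < cds_end && cds_end <= len)) {
      ff_format_error(paste0("CDS outside transcript bounds in ", transcript_id))
    }
    if ((cds_end - cds_start + 1L) %% 3L != 0L) {
      ff_format_error(paste0("CDS length not divisible by 3 in ", transcript_id))
    }
  }
  structure(list(
    gene_id = gene_id, gene_name = gene_name, transcript_id = transcript_id,
    contig = contig, strand = strand, exons = exons,
    cds_start = if (coding) as.integer(cds_start) else NA_integer_,
    cds_end = if (coding) as.integer(cds_end) else NA_integer_,
    coding = coding, length = as.integer(len)
  ), class = "transcript_model")
}

#' @export
print.transcript_model <- function(x, ...) {
  cat(sprintf(
    "<transcript_model> %s (%s) %s:%s strand %s\n  %d exon(s), length %d nt, %s\n",
    x$transcript_id, x$gene_name, x$contig,
    paste0(min(x$exons$start), "-", max(x$exons$end)), x$strand,
    nrow(x$exons), x$length,
    if (x$coding) sprintf("CDS %d-%d", x$cds_start, x$cds_end) else "non-coding"
  ))
  invisible(x)
}

#' Transcript length in nucleotides
#' @param model A `transcript_model`.
#' @return Integer length (sum of exon widths).
#' @export
transcript_length <- function(model) model$length

# Exons in transcript (5'->3') orientation: for minus-strand transcripts the
# genomically last exon comes first.
exons_in_transcript_order <- function(model) {
  ex <- model$exons
  if (model$strand == "-") ex <- ex[rev(seq_len(nrow(ex))), , drop = FALSE]
  rownames(ex) <- NULL
  ex
}

#' Load transcript models from a GTF file
#'
#' Reads `exon` and `CDS` features (GFF2/GTF dialect with `gene_id` and
#' `transcript_id` attributes) and builds one [transcript_model()] per
#' transcript. Genomic CDS intervals are converted into transcript
#' coordinates; transcripts without CDS features are flagged non-coding.
#'
#' @param path Path to a GTF file.
#' @return Named list of `transcript_model` objects (names = transcript ids).
#' @export
load_gene_models <- function(path) {
  if (!file.exists(path)) ff_format_error(paste0("GTF file not found: ", path))
  gr <- rtracklayer::import(path, format = "gtf")
  md <- S4Vectors::mcols(gr)
  if (is.null(md$transcript_id) || is.null(md$gene_id)) {
    ff_format_error("GTF lacks gene_id/transcript_id attributes")
  }
  keep <- md$type %in% c("exon", "CDS")
  gr <- gr[keep]
  md <- S4Vectors::mcols(gr)
  gene_name <- if (!is.null(md$gene_name)) md$gene_name else md$gene_id
  df <- data.frame(
    type = as.character(md$type),
    contig = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr), end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    gene_id = md$gene_id, gene_name = gene_name,
    transcript_id = md$transcript_id,
    stringsAsFactors = FALSE
  )
  models <- lapply(split(df, df$transcript_id), build_model_from_features)
  models[order(names(models))]
}

build_model_from_features <- function(feats) {
  tid <- feats$transcript_id[1L]
  ex <- feats[feats$type == "exon", , drop = FALSE]
  cds <- feats[feats$type == "CDS", , drop = FALSE]
  if (nrow(ex) == 0L) {
    ff_format_error(paste0("transcript ", tid, " has CDS but no exon features"))
  }
  strand <- ex$strand[1L]
  model <- transcript_model(
    gene_id = ex$gene_id[1L], gene_name = ex$gene_name[1L],
    transcript_id = tid, contig = ex$contig[1L], strand = strand,
    exons = ex[, c("start", "end")]
  )
  if (nrow(cds) == 0L) return(model)
  # convert the genomic CDS span to transcript coordinates; both CDS endpoints
  # must be exonic
  gfirst <- if (strand == "+") min(cds$start) else max(cds$end)
  glast <- if (strand == "+") max(cds$end) else min(cds$start)
  tfirst <- genomic_to_transcript(model, gfirst)
  tlast <- genomic_to_transcript(model, glast)
  if (tfirst$kind != "exonic" || tlast$kind != "exonic") {
    ff_format_error(paste0("CDS outside exons in transcript ", tid))
  }
  transcript_model(
    gene_id = model$gene_id, gene_name = model$gene_name,
    transcript_id = tid, contig = model$contig, strand = strand,
    exons = model$exons, cds_start = tfirst$tpos, cds_end = tlast$tpos
  )
}

#' Write transcript models to a GTF file
#'
#' Emits one `exon` line per exon and one `CDS` line per coding exon
#' segment, in the same GFF2/GTF dialect that [load_gene_models()] reads,
#' so that a write/load round trip reproduces identical models.
#'
#' @param models List of `transcript_model` objects.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gene_models <- function(models, path) {
  rows <- lapply(models, function(m) {
    attrs <- sprintf('gene_id "%s"; transcript_id "%s"; gene_name "%s";',
                     m$gene_id, m$transcript_id, m$gene_name)
    ex <- m$exons
    out <- data.frame(
      contig = m$contig, source = "fusionframe", type = "exon",
      start = ex$start, end = ex$end, score = ".", strand = m$strand,
      frame = ".", attrs = attrs, stringsAsFactors = FALSE
    )
    if (m$coding) {
      cds <- cds_genomic_segments(m)
      out <- rbind(out, data.frame(
        contig = m$contig, source = "fusionframe", type = "CDS",
        start = cds$start, end = cds$end, score = ".", strand = m$strand,
        frame = ".", attrs = attrs, stringsAsFactors = FALSE
      ))
    }
    out
  })
  tab <- do.call(rbind, rows)
  tab <- tab[order(tab$contig, tab$start, tab$type), , drop = FALSE]
  lines <- sprintf("%s\t%s\t%s\t%d\t%d\t%s\t%s\t%s\t%s",
                   tab$contig, tab$source, tab$type, tab$start, tab$end,
                   tab$score, tab$strand, tab$frame, tab$attrs)
  writeLines(lines, path)
  invisible(path)
}

# Genomic intervals covered by the CDS of a coding model (used for GTF export).
cds_genomic_segments <- function(model) {
  gpos <- vapply(model$cds_start:model$cds_end,
                 function(t) transcript_to_genomic(model, t), numeric(1))
  gpos <- sort(gpos)
  brk <- c(0L, which(diff(gpos) > 1L), length(gpos))
  data.frame(
    start = gpos[brk[-length(brk)] + 1L],
    end = gpos[brk[-1L]]
  )
}

#' Select the canonical transcript for a gene
#'
#' The canonical transcript is the one with the longest CDS; ties are broken
#' by the lexicographically smallest transcript id. Non-coding transcripts
#' count as CDS length 0.
#'
#' @param models Non-empty list of `transcript_model` objects for one gene.
#' @return A single `transcript_model`.
#' @export
select_canonical <- function(models) {
  if (length(models) == 0L) ff_stop("select_canonical: empty model collection")
  gid <- unique(vapply(models, `[[`, "", "gene_id"))
  if (length(gid) != 1L) ff_stop("select_canonical: models span multiple genes")
  cds_len <- vapply(models, function(m) {
    if (m$coding) m$cds_end - m$cds_start + 1L else 0L
  }, integer(1))
  tid <- vapply(models, `[[`, "", "transcript_id")
  models[[order(-cds_len, tid)[1L]]]
}

#' Map a genomic position onto a transcript
#'
#' @param model A `transcript_model`.
#' @param gpos Genomic position (1-based) on the model's contig.
#' @param contig Optional contig name; if supplied it must match the model's.
#' @return A list with `kind` one of `"exonic"`, `"intronic"`, `"outside"`;
#'   for exonic positions `tpos` holds the 1-based transcript coordinate, for
#'   intronic positions `intron` holds the intron index in transcript
#'   orientation (intron i follows exon i).
#' @export
genomic_to_transcript <- function(model, gpos, contig = NULL) {
  if (!is.null(contig) && contig != model$contig) {
    ff_stop(sprintf("position is on contig %s but transcript %s is on %s",
                    contig, model$transcript_id, model$contig))
  }
  ex <- exons_in_transcript_order(model)
  widths <- ex$end - ex$start + 1L
  offset <- cumsum(c(0L, widths))[seq_len(nrow(ex))]
  for (i in seq_len(nrow(ex))) {
    if (gpos >= ex$start[i] && gpos <= ex$end[i]) {
      tpos <- if (model$strand == "+") {
        offset[i] + (gpos - ex$start[i] + 1L)
      } else {
        offset[i] + (ex$end[i] - gpos + 1L)
      }
      return(list(kind = "exonic", tpos = as.integer(tpos)))
    }
  }
  if (gpos < min(model$exons$start) || gpos > max(model$exons$end)) {
    return(list(kind = "outside"))
  }
  # between exon i and i+1 in transcript orientation
  for (i in seq_len(nrow(ex) - 1L)) {
    if (model$strand == "+") {
      if (gpos > ex$end[i] && gpos < ex$start[i + 1L]) {
        return(list(kind = "intronic", intron = i))
      }
    } else {
      if (gpos < ex$start[i] && gpos > ex$end[i + 1L]) {
        return(list(kind = "intronic", intron = i))
      }
    }
  }
  list(kind = "outside")  # unreachable for well-formed models
}

#' Map a transcript position back to the genome
#'
#' Inverse of [genomic_to_transcript()] on exonic positions.
#'
#' @param model A `transcript_model`.
#' @param tpos Transcript coordinate, 1 <= tpos <= transcript length.
#' @return Genomic position (1-based).
#' @export
transcript_to_genomic <- function(model, tpos) {
  tpos <- as.integer(tpos)
  if (is.na(tpos) || tpos < 1L || tpos > model$length) {
    ff_stop(sprintf("transcript position %s out of range [1, %d] for %s",
                    tpos, model$length, model$transcript_id))
  }
  ex <- exons_in_transcript_order(model)
  widths <- ex$end - ex$start + 1L
  ends <- cumsum(widths)
  i <- which(tpos <= ends)[1L]
  within <- tpos - c(0L, ends)[i]
  if (model$strand == "+") ex$start[i] + within - 1L else ex$end[i] - within + 1L
}

#' Load a protein-domain table
#'
#' Reads a TSV with columns `gene_name`, `domain_name`, `aa_start`,
#' `aa_end` (protein coordinates, 1-based inclusive). Duplicate rows are
#' collapsed.
#'
#' @param path Path to the TSV file.
#' @return Data frame of validated, de-duplicated domain records.
#' @export
load_domain_table <- function(path) {
  if (!file.exists(path)) ff_format_error(paste0("domain table not found: ", path))
  tab <- read.delim(path, stringsAsFactors = FALSE)
  required <- c("gene_name", "domain_name", "aa_start", "aa_end")
  missing <- setdiff(required, names(tab))
  if (length(missing)) {
    ff_format_error(paste0("domain table missing column(s): ",
                           paste(missing, collapse = ", ")))
  }
  if (nrow(tab) == 0L) {
    return(tab[, required])
  }
  tab <- tab[, required]
  tab$aa_start <- as.integer(tab$aa_start)
  tab$aa_end <- as.integer(tab$aa_end)
  if (any(is.na(tab$aa_start)) || any(is.na(tab$aa_end))) {
    ff_format_error("non-numeric aa_start/aa_end in domain table")
  }
  if (any(tab$aa_start < 1L) || any(tab$aa_start > tab$aa_end)) {
    ff_format_error("invalid domain interval (need 1 <= aa_start <= aa_end)")
  }
  if (any(!nzchar(tab$domain_name))) ff_format_error("empty domain_name")
  tab <- unique(tab)
  rownames(tab) <- NULL
  tab
}

#' Write a protein-domain table
#' @param domains Data frame as returned by [load_domain_table()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_domain_table <- function(domains, path) {
  write.table(domains, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
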