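# Fusion-caller candidate tables: parsing, the spanning-read support
# filter, gene-pair collapsing and multi-caller consensus.

CANDIDATE_COLUMNS <- c("sample_id", "gene5", "contig5", "pos5",
                       "gene3", "contig3", "pos3", "spanning_reads")

#' Read fusion candidates from a TSV or BEDPE file
#'
#' The TSV format carries the columns `sample_id`, `gene5`, `contig5`,
#' `pos5`, `gene3`, `contig3`, `pos3`, `spanning_reads` and optionally
#' `provenance` (`"mrna"`/`"genomic"`, default `"genomic"`) and `caller`.
#' BEDPE input (`format = "bedpe"`) uses the standard 10+ column layout
#' (chrom1 start1 end1 chrom2 start2 end2 name score strand1 strand2, plus
#' optional `sample_id`, `spanning_reads`, `caller` columns); 0-based
#' half-open intervals are converted to 1-based inclusive positions, the
#' breakpoint taken as the end of the first interval and the start of the
#' second, and `name` split on `"--"` into the two gene symbols.
#'
#' @param path Input path.
#' @param format `"tsv"` or `"bedpe"`.
#' @return Data frame of candidates with the canonical column set.
#' @export
read_candidates <- function(path, format = c("tsv", "bedpe")) {
  format <- match.arg(format)
  if (!file.exists(path)) ff_format_error(paste0("candidate file not found: ", path))
  tab <- read.delim(path, stringsAsFactors = FALSE)
  if (format == "bedpe") {
    bed_required <- c("chrom1", "start1", "end1", "chrom2", "start2", "end2", "name")
    missing <- setdiff(bed_required, names(tab))
    if (length(missing)) {
      ff_format_error(paste0("BEDPE missing required column(s): ",
                             paste(missing, collapse = ", ")))
    }
    genes <- strsplit(tab$name, "--", fixed = TRUE)
    if (any(lengths(genes) != 2L)) {
      ff_format_error('BEDPE name column must be "GENE5--GENE3"')
    }
    tab <- data.frame(
      sample_id = if (!is.null(tab$sample_id)) tab$sample_id else "sample1",
      gene5 = vapply(genes, `[`, "", 1L),
      contig5 = tab$chrom1,
      # BEDPE end is 0-based exclusive == 1-based inclusive last base
      pos5 = as.integer(tab$end1),
      gene3 = vapply(genes, `[`, "", 2L),
      contig3 = tab$chrom2,
      # BEDPE start is 0-based inclusive -> +1 for 1-based first base
      pos3 = as.integer(tab$start2) + 1L,
      spanning_reads = if (!is.null(tab$spanning_reads)) {
        as.integer(tab$spanning_reads)
      } else {
        0L
      },
      caller = if (!is.null(tab$caller)) tab$caller else NA_character_,
      provenance = "genomic",
      stringsAsFactors = FALSE
    )
    return(validate_candidates(tab))
  }
  missing <- setdiff(CANDIDATE_COLUMNS, names(tab))
  if (length(missing)) {
    ff_format_error(paste0("candidate table missing required column(s): ",
                           paste(missing, collapse = ", ")))
  }
  if (is.null(tab$provenance)) tab$provenance <- "genomic"
  if (is.null(tab$caller)) tab$caller <- NA_character_
  validate_candidates(tab[, c(CANDIDATE_COLUMNS, "provenance", "caller")])
}

validate_candidates <- function(tab) {
  tab$pos5 <- as.numeric(tab$pos5)
  tab$pos3 <- as.numeric(tab$pos3)
  tab$spanning_reads <- as.integer(tab$spanning_reads)
  if (any(is.na(tab$spanning_reads)) || any(tab$spanning_reads < 0L)) {
    ff_format_error("spanning_reads must be a non-negative integer")
  }
  if (any(!nzchar(tab$sample_id))) ff_format_error("empty sample_id")
  if (any(tab$pos5 < 1) || any(tab$pos3 < 1)) {
    ff_format_error("breakpoint positions must be positive")
  }
  rownames(tab) <- NULL
  tab
}

#' Write candidates to TSV
#' @param candidates Candidate data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_candidates <- function(candidates, path) {
  write.table(candidates, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Filter candidates by spanning-read support
#'
#' Keeps candidates whose junction-spanning read count is *strictly*
#' greater than `threshold` (default 3, i.e. "> 3 spanning reads").
#'
#' @param candidates Candidate data frame.
#' @param threshold Minimum excluded support level.
#' @return Filtered data frame (subset of the input rows).
#' @export
filter_by_spanning_reads <- function(candidates, threshold = 3L) {
  out <- candidates[candidates$spanning_reads > threshold, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Collapse breakpoint-level candidates to gene-pair fusion events
#'
#' Fusions are identified at the level of the ordered gene pair: distinct
#' mRNA breakpoints observed for the same (sample, gene5, gene3) key are
#' breakpoint isoforms of one fusion event. `(A, B)` and `(B, A)` are
#' different fusions.
#'
#' @param candidates Candidate data frame.
#' @return Data frame with one row per (sample_id, gene5, gene3):
#'   `n_isoforms`, `breakpoints` (semicolon-joined `pos5|pos3` pairs sorted
#'   by position) and `max_spanning_reads`.
#' @export
collapse_by_gene_pair <- function(candidates) {
  if (nrow(candidates) == 0L) {
    return(data.frame(sample_id = character(), gene5 = character(),
                      gene3 = character(), n_isoforms = integer(),
                      breakpoints = character(),
                      max_spanning_reads = integer(),
                      stringsAsFactors = FALSE))
  }
  key <- interaction(candidates$sample_id, candidates$gene5,
                     candidates$gene3, drop = TRUE, sep = "\r")
  rows <- lapply(split(candidates, key), function(grp) {
    ord <- order(grp$pos5, grp$pos3)
    grp <- grp[ord, , drop = FALSE]
    iso <- unique(paste0(grp$pos5, "|", grp$pos3))
    data.frame(
      sample_id = grp$sample_id[1L], gene5 = grp$gene5[1L],
      gene3 = grp$gene3[1L], n_isoforms = length(iso),
      breakpoints = paste(iso, collapse = ";"),
      max_spanning_reads = max(grp$spanning_reads),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$gene5, out$gene3, out$sample_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Multi-caller consensus of fusion candidates
#'
#' Matches candidates across callers by (sample, ordered gene pair) —
#' caller breakpoint estimates routinely differ by a few bases, so exact
#' coordinates are deliberately not part of the key.
#'
#' @param candidate_sets Named list of candidate data frames, one per
#'   caller (names are the caller labels).
#' @param mode `"union"` keeps every pair and annotates its support count;
#'   `"intersection"` keeps pairs reported by at least `min_callers`
#'   callers.
#' @param min_callers Support required in intersection mode (default 2).
#' @return Data frame with one row per (sample_id, gene5, gene3):
#'   `callers` (comma-joined), `n_callers`, and `max_spanning_reads`.
#' @export
caller_consensus <- function(candidate_sets, mode = c("union", "intersection"),
                             min_callers = 2L) {
  mode <- match.arg(mode)
  if (length(candidate_sets) == 0L) ff_stop("caller_consensus: no candidate sets")
  if (is.null(names(candidate_sets)) || any(!nzchar(names(candidate_sets)))) {
    names(candidate_sets) <- paste0("caller", seq_along(candidate_sets))
  }
  all <- do.call(rbind, lapply(names(candidate_sets), function(cl) {
    cs <- candidate_sets[[cl]]
    if (nrow(cs) == 0L) return(NULL)
    data.frame(sample_id = cs$sample_id, gene5 = cs$gene5, gene3 = cs$gene3,
               spanning_reads = cs$spanning_reads, caller = cl,
               stringsAsFactors = FALSE)
  }))
  if (is.null(all) || nrow(all) == 0L) {
    return(data.frame(sample_id = character(), gene5 = character(),
                      gene3 = character(), callers = character(),
                      n_callers = integer(), max_spanning_reads = integer(),
                      stringsAsFactors = FALSE))
  }
  key <- interaction(all$sample_id, all$gene5, all$gene3, drop = TRUE, sep = "\r")
  rows <- lapply(split(all, key), function(grp) {
    callers <- sort(unique(grp$caller))
    data.frame(
      sample_id = grp$sample_id[1L], gene5 = grp$gene5[1L],
      gene3 = grp$gene3[1L], callers = paste(callers, collapse = ","),
      n_callers = length(callers),
      max_spanning_reads = max(grp$spanning_reads),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  if (mode == "intersection") {
    out <- out[out$n_callers >= min_callers, , drop = FALSE]
  }
  out <- out[order(out$gene5, out$gene3, out$sample_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Flag possible read-through transcripts
#'
#' Candidates whose partners sit on the same contig within `max_distance`
#' (default 100 kb) with the 5' partner breakpoint upstream of the 3'
#' partner breakpoint are flagged as possible read-throughs. This is an
#' annotation only — such candidates are never dropped automatically.
#'
#' @param candidates Candidate data frame.
#' @param max_distance Maximum genomic separation in bp.
#' @return The input with a logical `possible_read_through` column added.
#' @export
flag_read_through <- function(candidates, max_distance = 1e5) {
  same <- candidates$contig5 == candidates$contig3
  dist <- abs(candidates$pos3 - candidates$pos5)
  upstream <- candidates$pos5 < candidates$pos3
  candidates$possible_read_through <- same & upstream & dist <= max_distance
  candidates
}
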