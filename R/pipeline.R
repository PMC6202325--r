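# Orchestration: validated run configuration and the end-to-end pipeline
# (intake -> annotation -> expression -> cohort statistics -> survival),
# producing report tables shaped like the result tables of a fusion
# cohort study plus a machine-readable JSON summary.

RUN_CONFIG_KEYS <- c(
  "genome", "gtf", "domains", "candidates", "exon_matrix", "cohort",
  "outdir", "spanning_read_threshold", "recurrence_min_samples",
  "chi_square_correction", "cox_ties", "seed", "fusion_flags",
  "mutation_flags", "log_level"
)

RUN_CONFIG_DEFAULTS <- list(
  spanning_read_threshold = 3L,
  recurrence_min_samples = 2L,
  chi_square_correction = FALSE,
  cox_ties = "efron",
  seed = 1L,
  mutation_flags = c("CDH1", "RHOA"),
  log_level = "info"
)

#' Validate a pipeline run configuration
#'
#' Reads a YAML file (or takes a named list), checks every key against the
#' known set, fills defaults, and verifies that all referenced input paths
#' exist.
#'
#' @param config Path to a YAML file or a named list.
#' @return A validated `run_config` list with defaults filled in.
#' @export
validate_config <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config)) ff_stop(paste0("config file not found: ", config))
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config)) ff_stop("config must be a file path or a named list")
  unknown <- setdiff(names(config), RUN_CONFIG_KEYS)
  if (length(unknown)) {
    ff_stop(paste0("unknown config key(s): ", paste(unknown, collapse = ", ")))
  }
  for (key in names(RUN_CONFIG_DEFAULTS)) {
    if (is.null(config[[key]])) config[[key]] <- RUN_CONFIG_DEFAULTS[[key]]
  }
  required_paths <- c("genome", "gtf", "domains", "candidates", "cohort")
  for (key in required_paths) {
    if (is.null(config[[key]])) ff_stop(paste0("config missing required path: ", key))
    if (!file.exists(config[[key]])) {
      ff_stop(paste0("config path does not exist (", key, "): ", config[[key]]))
    }
  }
  if (!is.null(config$exon_matrix) && !file.exists(config$exon_matrix)) {
    ff_stop(paste0("config path does not exist (exon_matrix): ", config$exon_matrix))
  }
  if (config$spanning_read_threshold < 0) {
    ff_stop("spanning_read_threshold must be >= 0")
  }
  if (config$recurrence_min_samples < 1) {
    ff_stop("recurrence_min_samples must be >= 1")
  }
  if (!config$cox_ties %in% c("efron", "breslow")) {
    ff_stop('cox_ties must be "efron" or "breslow"')
  }
  structure(config, class = "run_config")
}

pipeline_log <- function(config, ...) {
  if (identical(config$log_level, "quiet")) return(invisible())
  message(sprintf("[fusionframe] %s", sprintf(...)))
}

#' Run the full fusion-annotation and cohort-statistics pipeline
#'
#' Stages: (1) read and filter fusion candidates by spanning-read support
#' and collapse them to gene-pair events; (2) annotate every retained
#' candidate (frame status, retained spans, retained domains, class
#' labels); (3) score breakpoint-consistent 3' expression imbalance and
#' outlier ranks for in-frame fusions when an exon matrix is supplied;
#' (4) recurrence, prevalence and mutual-exclusivity statistics on the
#' cohort; (5) Kaplan-Meier, log-rank and Cox analyses of fusion carriers.
#' All results are written as TSV/JSON into `outdir`.
#'
#' @param config A `run_config` from [validate_config()] (or anything it
#'   accepts).
#' @return Invisibly, a list with all report components.
#' @export
run_pipeline <- function(config) {
  config <- validate_config(config)
  outdir <- if (is.null(config$outdir)) "." else config$outdir
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)

  pipeline_log(config, "loading reference inputs")
  genome <- load_genome(config$genome)
  models <- load_gene_models(config$gtf)
  domains <- load_domain_table(config$domains)
  cohort <- read_cohort(config$cohort)

  pipeline_log(config, "stage 1: candidate intake (threshold > %d spanning reads)",
               config$spanning_read_threshold)
  candidates <- read_candidates(config$candidates)
  kept <- filter_by_spanning_reads(candidates, config$spanning_read_threshold)
  events <- collapse_by_gene_pair(kept)

  pipeline_log(config, "stage 2: annotating %d candidate rows", nrow(kept))
  annotations <- lapply(seq_len(nrow(kept)), function(i) {
    annotate_candidate(kept[i, ], models, domains, genome)
  })
  annotation_tab <- annotation_table(annotations)

  in_frame <- annotation_tab[annotation_tab$frame_status == "IN_FRAME", ,
                             drop = FALSE]

  expression_tab <- NULL
  if (!is.null(config$exon_matrix)) {
    pipeline_log(config, "stage 3: expression imbalance for %d in-frame rows",
                 nrow(in_frame))
    mat <- read_exon_matrix(config$exon_matrix)
    centered <- center_by_gene(mat)
    rows <- lapply(seq_len(nrow(in_frame)), function(i) {
      row <- in_frame[i, ]
      m3 <- canonical_for_gene(models, row$gene3)
      t3 <- genomic_to_transcript(m3, row$mrna_bp3)
      k <- exon_index_of_tpos(m3, t3$tpos)
      imb <- tryCatch(
        breakpoint_imbalance_score(centered, row$gene3, k, row$sample_id),
        fusionframe_error = function(e) NULL
      )
      rank <- outlier_rank(gene_level_expression(mat, row$gene3), row$sample_id)
      data.frame(
        sample_id = row$sample_id, fusion = paste0(row$gene5, "-", row$gene3),
        gene3 = row$gene3, breakpoint_exon = k,
        imbalance_score = if (is.null(imb)) NA_real_ else imb$score,
        imbalance_z = if (is.null(imb)) NA_real_ else imb$z,
        outlier_rank = rank$rank, n_ranked = rank$n,
        stringsAsFactors = FALSE
      )
    })
    expression_tab <- do.call(rbind, rows)
  }

  pipeline_log(config, "stage 4: cohort statistics")
  fusion_flags <- if (!is.null(config$fusion_flags)) {
    config$fusion_flags
  } else {
    sub("^fusion_", "", grep("^fusion_", names(cohort), value = TRUE))
  }
  fusion_flags <- setdiff(fusion_flags, "any")
  per_fusion_counts <- vapply(fusion_flags, function(f) {
    sum(cohort[[paste0("fusion_", f)]] %in% TRUE)
  }, integer(1))
  recurrent <- find_recurrent(per_fusion_counts, config$recurrence_min_samples)
  prevalence <- fusion_prevalence(cohort, fusion_flags)
  exclusivity <- lapply(config$mutation_flags, function(flag) {
    if (!flag %in% names(cohort)) return(NULL)
    mutual_exclusivity_report(cohort, fusion_flags, flag)
  })
  names(exclusivity) <- config$mutation_flags
  exclusivity <- Filter(Negate(is.null), exclusivity)

  pipeline_log(config, "stage 5: survival")
  carrier <- rowSums(sapply(fusion_flags, function(f) {
    cohort[[paste0("fusion_", f)]] %in% TRUE
  })) > 0
  km_pos <- km_estimate(cohort$survival_months[carrier], cohort$event[carrier])
  km_neg <- km_estimate(cohort$survival_months[!carrier], cohort$event[!carrier])
  lr <- log_rank(cohort$survival_months, cohort$event,
                 ifelse(carrier, "fusion", "no_fusion"))
  cox_uni <- cox_fit(cohort$survival_months, cohort$event,
                     data.frame(fusion = as.numeric(carrier)),
                     ties = config$cox_ties)
  cox_multi <- NULL
  multi_flags <- intersect(c("CIN", "CDH1"), names(cohort))
  if (length(multi_flags)) {
    covs <- data.frame(fusion = as.numeric(carrier))
    for (flag in multi_flags) covs[[flag]] <- as.numeric(cohort[[flag]])
    complete <- complete.cases(covs)
    if (sum(cohort$event[complete]) >= 2L) {
      cox_multi <- tryCatch(
        cox_fit(cohort$survival_months[complete], cohort$event[complete],
                covs[complete, , drop = FALSE], ties = config$cox_ties),
        fusionframe_error = function(e) NULL
      )
    }
  }

  report <- list(
    annotations = annotation_tab,
    events = events,
    expression = expression_tab,
    prevalence = prevalence,
    per_fusion_counts = per_fusion_counts,
    recurrent = recurrent,
    exclusivity = exclusivity,
    km = list(fusion = km_pos, no_fusion = km_neg),
    log_rank = lr,
    cox_univariate = cox_uni,
    cox_multivariable = cox_multi
  )
  write_report(report, outdir, config)
  invisible(report)
}

annotation_table <- function(annotations) {
  rows <- lapply(annotations, function(a) {
    data.frame(
      sample_id = a$sample_id, gene5 = a$gene5, gene3 = a$gene3,
      mrna_bp5 = a$mrna_bp5, mrna_bp3 = a$mrna_bp3,
      frame_status = a$frame_status,
      n5_cds = a$n5_cds, d3_offset = a$d3_offset,
      aa5_span = span_label(a$aa5_span), aa3_span = span_label(a$aa3_span),
      retained_domains = paste(
        paste0(a$retained_domains$domain_name, " (",
               ifelse(a$retained_domains$side == "3p", "3'", "5'"), ")"),
        collapse = "; "
      ),
      class_labels = paste(a$class_labels, collapse = "; "),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

span_label <- function(span) {
  if (is.null(span)) "" else paste0(span[1L], "-", span[2L])
}

write_report <- function(report, outdir, config) {
  write.table(report$annotations, file.path(outdir, "annotations.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(report$events, file.path(outdir, "fusion_events.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(report$expression)) {
    write.table(report$expression, file.path(outdir, "expression_imbalance.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }
  km_points <- rbind(
    cbind(group = "fusion", report$km$fusion$curve),
    cbind(group = "no_fusion", report$km$no_fusion$curve)
  )
  write.table(km_points, file.path(outdir, "km_curves.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  summary <- list(
    settings = list(
      spanning_read_threshold = config$spanning_read_threshold,
      recurrence_min_samples = config$recurrence_min_samples,
      chi_square_correction = config$chi_square_correction,
      cox_ties = config$cox_ties
    ),
    n_candidates_kept = nrow(report$annotations),
    n_in_frame = sum(report$annotations$frame_status == "IN_FRAME"),
    per_fusion_counts = as.list(report$per_fusion_counts),
    recurrent_fusions = report$recurrent,
    prevalence = report$prevalence,
    exclusivity = lapply(report$exclusivity, function(x) {
      list(table = c(a = x$a, b = x$b, c = x$c, d = x$d),
           frac_mutated_fusion_neg = x$frac_mutated_fusion_neg,
           chi_square_p = x$chi_square$p, fisher_p = x$fisher$p)
    }),
    survival = list(
      median_fusion = report$km$fusion$median,
      median_no_fusion = report$km$no_fusion$median,
      log_rank_p = report$log_rank$p,
      hr_univariate = unname(report$cox_univariate$hr["fusion"]),
      hr_univariate_ci = c(unname(report$cox_univariate$ci_lower["fusion"]),
                           unname(report$cox_univariate$ci_upper["fusion"])),
      hr_adjusted = if (!is.null(report$cox_multivariable)) {
        unname(report$cox_multivariable$hr["fusion"])
      } else {
        NULL
      }
    )
  )
  jsonlite::write_json(summary, file.path(outdir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null")
  invisible()
}
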