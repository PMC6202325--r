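# Cohort-level statistics: prevalence and recurrence counting, 2x2
# association tests and the rank-sum test. The test statistics are computed
# from first principles; only the reference distributions (chi-square,
# hypergeometric, Wilcoxon, normal) come from base R.

#' Read a cohort table from TSV
#'
#' Required columns: `sample_id`, `survival_months`, `event`. Fusion status
#' columns are named `fusion_<NAME>`; molecular flags (e.g. `CDH1`,
#' `RHOA`, `TP53`, `CIN`) and other clinical columns are passed through.
#' Logical columns may be coded TRUE/FALSE, 1/0; missing flags stay `NA`.
#'
#' @param path Input TSV path.
#' @return Data frame with one row per sample.
#' @export
read_cohort <- function(path) {
  if (!file.exists(path)) ff_format_error(paste0("cohort table not found: ", path))
  tab <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  required <- c("sample_id", "survival_months", "event")
  missing <- setdiff(required, names(tab))
  if (length(missing)) {
    ff_format_error(paste0("cohort table missing column(s): ",
                           paste(missing, collapse = ", ")))
  }
  if (anyDuplicated(tab$sample_id)) ff_format_error("duplicate sample_id in cohort")
  if (any(tab$survival_months < 0, na.rm = TRUE)) {
    ff_format_error("negative survival_months")
  }
  tab
}

#' Write a cohort table to TSV
#' @param cohort Cohort data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  write.table(cohort, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Round half-up to a number of decimals
#'
#' Percentages in cohort reports are rounded half-up (so 4.35 -> 4.4),
#' unlike base `round()`'s round-half-even.
#'
#' @param x Numeric vector.
#' @param digits Decimal places.
#' @return Rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 1L) {
  scale <- 10^digits
  floor(x * scale + 0.5) / scale
}

#' Prevalence of a set of fusions in a cohort
#'
#' Counts samples positive for at least one of the named fusions.
#'
#' @param cohort Cohort data frame with `fusion_<NAME>` columns.
#' @param fusion_names Character vector of fusion names (without the
#'   `fusion_` prefix); may be empty.
#' @return List with `count`, `n` and `percent` (half-up, 1 decimal).
#' @export
fusion_prevalence <- function(cohort, fusion_names) {
  n <- nrow(cohort)
  if (length(fusion_names) == 0L) {
    return(list(count = 0L, n = n, percent = 0))
  }
  cols <- paste0("fusion_", fusion_names)
  missing <- setdiff(cols, names(cohort))
  if (length(missing)) {
    ff_stop(paste0("unknown fusion column(s): ", paste(missing, collapse = ", ")))
  }
  pos <- rowSums(sapply(cols, function(cl) cohort[[cl]] %in% TRUE)) > 0
  count <- sum(pos)
  list(count = as.integer(count), n = n,
       percent = round_half_up(100 * count / n, 1L))
}

#' Recurrent fusions
#'
#' A fusion is recurrent when present in at least `min_samples` *distinct
#' samples* (breakpoint isoforms within one sample do not count twice).
#'
#' @param sample_counts Named integer vector: fusions -> number of distinct
#'   positive samples.
#' @param min_samples Recurrence threshold (default 2).
#' @return Character vector of recurrent fusion names (sorted).
#' @export
find_recurrent <- function(sample_counts, min_samples = 2L) {
  sort(names(sample_counts)[sample_counts >= min_samples])
}

#' Pearson chi-square test on a 2x2 table
#'
#' Uncorrected Pearson chi-square (no Yates continuity correction): the
#' statistic is `sum((O - E)^2 / E)` over the four cells, equivalently
#' `n (ad - bc)^2` over the product of the marginals, with 1 degree of
#' freedom. The continuity-corrected variant is available via
#' `correct = TRUE`.
#'
#' @param a,b,c,d Cell counts: rows are groups, columns outcomes
#'   (`a`,`b` = row 1; `c`,`d` = row 2).
#' @param correct Apply the Yates continuity correction.
#' @return List with `statistic`, `df` and `p`.
#' @export
chi_square_2x2 <- function(a, b, c, d, correct = FALSE) {
  if (any(c(a, b, c, d) < 0)) ff_stop("negative cell count")
  n <- a + b + c + d
  m <- c(a + b, c + d, a + c, b + d)
  if (any(m == 0)) ff_stop("chi-square undefined: zero marginal total")
  delta <- abs(a * d - b * c)
  if (correct) delta <- max(0, delta - n / 2)
  stat <- n * delta^2 / prod(m)
  list(statistic = stat, df = 1L, p = pchisq(stat, df = 1L, lower.tail = FALSE))
}

#' Fisher's exact test on a 2x2 table
#'
#' Conditional on both margins, the probability of each admissible table is
#' hypergeometric; the two-sided p-value sums the probabilities of all
#' tables no more probable than the observed one (the convention used by
#' `stats::fisher.test`). One-sided variants sum the corresponding tail.
#'
#' @param a,b,c,d Cell counts as in [chi_square_2x2()].
#' @param alternative `"two.sided"`, `"less"` or `"greater"` (refers to the
#'   `a` cell).
#' @return List with `p`.
#' @export
fisher_exact_2x2 <- function(a, b, c, d,
                             alternative = c("two.sided", "less", "greater")) {
  alternative <- match.arg(alternative)
  if (any(c(a, b, c, d) < 0)) ff_stop("negative cell count")
  m <- a + b      # row-1 total
  k <- a + c      # column-1 total
  n2 <- c + d     # row-2 total
  lo <- max(0L, k - n2)
  hi <- min(m, k)
  support <- lo:hi
  probs <- dhyper(support, m, n2, k)
  p_obs <- dhyper(a, m, n2, k)
  p <- switch(alternative,
    two.sided = sum(probs[probs <= p_obs * (1 + 1e-7)]),
    less = sum(probs[support <= a]),
    greater = sum(probs[support >= a])
  )
  list(p = min(1, p))
}

#' Wilcoxon rank-sum (Mann-Whitney) test
#'
#' Computes the rank-sum statistic `W` (number of pairs where an `x` value
#' exceeds a `y` value, counting ties as half). With no ties and small
#' samples the p-value is exact (from the Wilcoxon distribution); with
#' ties or large samples a normal approximation with tie-corrected
#' variance is used.
#'
#' @param x,y Numeric vectors, both non-empty.
#' @param exact_max Use the exact distribution when both group sizes are
#'   below this and there are no ties (default 50, the `wilcox.test`
#'   convention).
#' @return List with `statistic` (W), `p` and `method`.
#' @export
wilcoxon_rank_sum <- function(x, y, exact_max = 50L) {
  if (length(x) == 0L || length(y) == 0L) ff_stop("both groups must be non-empty")
  nx <- length(x)
  ny <- length(y)
  r <- rank(c(x, y))
  W <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  ties <- table(r)
  has_ties <- any(ties > 1)
  if (length(unique(c(x, y))) == 1L) {
    return(list(statistic = W, p = 1, method = "degenerate"))
  }
  if (!has_ties && nx < exact_max && ny < exact_max) {
    p <- if (W > nx * ny / 2) {
      2 * (1 - pwilcox(W - 1, nx, ny))
    } else {
      2 * pwilcox(W, nx, ny)
    }
    return(list(statistic = W, p = min(1, p), method = "exact"))
  }
  mu <- nx * ny / 2
  sigma2 <- nx * ny / 12 *
    ((nx + ny + 1) - sum(ties^3 - ties) / ((nx + ny) * (nx + ny - 1)))
  z <- (W - mu) / sqrt(sigma2)
  list(statistic = W, p = min(1, 2 * pnorm(-abs(z))),
       method = "normal approximation")
}

#' Mutual-exclusivity report for a fusion set against a mutation flag
#'
#' Builds the 2x2 table of fusion status against a molecular flag over the
#' samples where the flag is non-missing (test-wise exclusion) and runs
#' both the uncorrected chi-square and Fisher's exact test.
#'
#' @param cohort Cohort data frame.
#' @param fusion_names Fusions defining the positive group (any-of).
#' @param flag Name of the logical mutation-flag column (e.g. `"CDH1"`).
#' @return List with the 2x2 cells (`a` = fusion+/mutated, `b` =
#'   fusion+/wild-type, `c` = fusion-/mutated, `d` = fusion-/wild-type),
#'   the fraction mutated in each group, and `chi_square` / `fisher`
#'   results.
#' @export
mutual_exclusivity_report <- function(cohort, fusion_names, flag) {
  if (!flag %in% names(cohort)) ff_stop(paste0("unknown flag column: ", flag))
  cols <- paste0("fusion_", fusion_names)
  missing <- setdiff(cols, names(cohort))
  if (length(missing)) {
    ff_stop(paste0("unknown fusion column(s): ", paste(missing, collapse = ", ")))
  }
  pos <- rowSums(sapply(cols, function(cl) cohort[[cl]] %in% TRUE)) > 0
  flag_val <- cohort[[flag]]
  keep <- !is.na(flag_val)
  if (sum(keep) < 2L) ff_stop("fewer than 2 samples with a non-missing flag")
  pos <- pos[keep]
  mut <- flag_val[keep] %in% TRUE
  a <- sum(pos & mut)
  b <- sum(pos & !mut)
  c <- sum(!pos & mut)
  d <- sum(!pos & !mut)
  list(
    a = a, b = b, c = c, d = d,
    frac_mutated_fusion_pos = if (a + b > 0) a / (a + b) else NA_real_,
    frac_mutated_fusion_neg = if (c + d > 0) c / (c + d) else NA_real_,
    chi_square = chi_square_2x2(a, b, c, d),
    fisher = fisher_exact_2x2(a, b, c, d)
  )
}
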