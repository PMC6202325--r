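# Counting and association tests on cohort tables.

# Build a cohort of n samples with the given number of positives per fusion
# (disjoint) and optional mutation counts among fusion +/- groups.
counts_cohort <- function(n, fusion_pos = integer(0), flag = NULL,
                          flag_pos_mut = 0L, flag_neg_mut = 0L,
                          flag_neg_total = NULL) {
  cohort <- data.frame(sample_id = paste0("S", seq_len(n)),
                       survival_months = 1, event = FALSE,
                       stringsAsFactors = FALSE)
  at <- 0L
  for (f in names(fusion_pos)) {
    v <- rep(FALSE, n)
    v[at + seq_len(fusion_pos[[f]])] <- TRUE
    at <- at + fusion_pos[[f]]
    cohort[[paste0("fusion_", f)]] <- v
  }
  if (!is.null(flag)) {
    pos <- rowSums(cohort[, grep("^fusion_", names(cohort)), drop = FALSE]) > 0
    v <- rep(NA, n)
    ip <- which(pos)
    im <- which(!pos)
    if (is.null(flag_neg_total)) flag_neg_total <- length(im)
    v[ip] <- c(rep(TRUE, flag_pos_mut),
               rep(FALSE, length(ip) - flag_pos_mut))
    v[im[seq_len(flag_neg_total)]] <- c(rep(TRUE, flag_neg_mut),
                                        rep(FALSE, flag_neg_total - flag_neg_mut))
    cohort[[flag]] <- v
  }
  cohort
}

test_that("fusion prevalence reproduces the printed cohort fractions", {
  coh <- counts_cohort(384, c(F1 = 13L, F2 = 2L, F3 = 2L))
  res <- fusion_prevalence(coh, c("F1", "F2", "F3"))
  expect_identical(res$count, 17L)
  expect_identical(res$percent, 4.4)
  expect_identical(fusion_prevalence(coh, "F1")$percent, 3.4)

  coh305 <- counts_cohort(305, c(FX = 3L))
  expect_identical(fusion_prevalence(coh305, "FX")$percent, 1.0)

  expect_identical(fusion_prevalence(coh, character(0)),
                   list(count = 0L, n = 384L, percent = 0))
  expect_error(fusion_prevalence(coh, "NOPE"), "unknown fusion")
})

test_that("percent rounding is half-up and prevalence is additive before rounding", {
  expect_identical(round_half_up(0.05 * 100 / 100, 1), 0.1)
  expect_identical(round_half_up(4.45, 1), 4.5)
  coh <- counts_cohort(384, c(A = 13L, B = 2L, C = 2L))
  p_all <- fusion_prevalence(coh, c("A", "B", "C"))
  counts <- vapply(c("A", "B", "C"), function(f)
    fusion_prevalence(coh, f)$count, integer(1))
  expect_identical(sum(counts), p_all$count)  # disjoint sets are additive
})

test_that("recurrence is counted over distinct samples with threshold 2", {
  expect_identical(find_recurrent(c(F1 = 13L, F2 = 2L, F3 = 2L, F4 = 1L)),
                   c("F1", "F2", "F3"))
  expect_identical(find_recurrent(c(A = 1L, B = 1L)), character(0))
  # two isoforms in one sample still count as one sample
  cands <- data.frame(sample_id = "S1", gene5 = "A", contig5 = "c", pos5 = c(10, 11),
                      gene3 = "B", contig3 = "c", pos3 = c(99, 99),
                      spanning_reads = 9L, stringsAsFactors = FALSE)
  ev <- collapse_by_gene_pair(cands)
  counts <- table(paste0(ev$gene5, "-", ev$gene3))
  expect_identical(find_recurrent(setNames(as.integer(counts), names(counts))),
                   character(0))
})

test_that("uncorrected Pearson chi-square reproduces the printed exclusivity P values", {
  r1 <- chi_square_2x2(0, 17, 66, 146)
  expect_equal(r1$statistic, 7.435, tolerance = 1e-3)
  expect_equal(round(r1$p, 3), 0.006)
  r2 <- chi_square_2x2(0, 17, 32, 180)
  expect_equal(round(r2$p, 2), 0.08)
  r3 <- chi_square_2x2(8, 127, 5, 244)
  expect_equal(round(r3$p, 3), 0.043)
  # perfectly proportional table
  r0 <- chi_square_2x2(10, 20, 30, 60)
  expect_equal(r0$statistic, 0)
  expect_equal(r0$p, 1)
  expect_error(chi_square_2x2(0, 0, 5, 5), "marginal")
})

test_that("chi-square matches Sum((O-E)^2/E) and stats::chisq.test on random tables", {
  set.seed(77)
  for (i in 1:40) {
    cells <- sample(1:60, 4, replace = TRUE)
    mine <- chi_square_2x2(cells[1], cells[2], cells[3], cells[4])
    # independent oracle: expected counts from the marginals
    tab <- matrix(cells, 2, byrow = TRUE)
    E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
    expect_equal(mine$statistic, sum((tab - E)^2 / E), tolerance = 1e-10)
    ref <- suppressWarnings(chisq.test(tab, correct = FALSE))
    expect_equal(mine$p, ref$p.value, tolerance = 1e-10)
    refc <- suppressWarnings(chisq.test(tab, correct = TRUE))
    expect_equal(chi_square_2x2(cells[1], cells[2], cells[3], cells[4],
                                correct = TRUE)$p,
                 refc$p.value, tolerance = 1e-10)
  }
})

test_that("Fisher's exact test matches enumeration and handles zero margins", {
  expect_equal(fisher_exact_2x2(1, 9, 11, 3)$p, 0.002759456, tolerance = 1e-6)
  expect_equal(fisher_exact_2x2(5, 0, 7, 0)$p, 1)
  set.seed(31)
  for (i in 1:40) {
    cells <- sample(0:8, 4, replace = TRUE)
    if (sum(cells) == 0) next
    mine <- fisher_exact_2x2(cells[1], cells[2], cells[3], cells[4])$p
    ref <- fisher.test(matrix(cells, 2, byrow = TRUE))$p.value
    expect_equal(mine, ref, tolerance = 1e-9)
  }
  # asymptotic agreement on a large balanced table
  pc <- chi_square_2x2(300, 200, 260, 240)$p
  pf <- fisher_exact_2x2(300, 200, 260, 240)$p
  expect_lt(abs(pf - pc) / pc, 0.2)
})

test_that("Wilcoxon rank-sum: exact for small untied samples, calibrated otherwise", {
  res <- wilcoxon_rank_sum(c(1, 2, 3), c(4, 5, 6))
  expect_equal(res$p, 0.1)  # most extreme of the 20 rank assignments
  expect_identical(res$method, "exact")
  # independent enumeration oracle over all choose(6, 3) assignments
  vals <- c(1, 2, 3, 4, 5, 6)
  combos <- combn(6, 3)
  w_obs <- sum(rank(vals)[1:3]) - 6
  w_all <- apply(combos, 2, function(idx) sum(rank(vals)[idx]) - 6)
  mu <- 9 / 2
  p_enum <- mean(abs(w_all - mu) >= abs(w_obs - mu))
  expect_equal(res$p, p_enum)

  expect_equal(wilcoxon_rank_sum(c(2, 2, 2), c(2, 2))$p, 1)

  set.seed(13)
  for (i in 1:20) {
    x <- rnorm(sample(4:30, 1))
    y <- rnorm(sample(4:30, 1), mean = runif(1, -1, 1))
    mine <- wilcoxon_rank_sum(x, y)
    ref <- wilcox.test(x, y, exact = TRUE)
    expect_equal(mine$statistic, unname(ref$statistic))
    expect_equal(mine$p, ref$p.value, tolerance = 1e-9)
  }
  # ties take the tie-corrected normal path, matching wilcox.test(correct=FALSE)
  x <- c(1, 2, 2, 3, 5, 5, 6)
  y <- c(2, 3, 3, 4, 5, 7, 8)
  mine <- wilcoxon_rank_sum(x, y)
  ref <- suppressWarnings(wilcox.test(x, y, exact = FALSE, correct = FALSE))
  expect_equal(mine$p, ref$p.value, tolerance = 1e-9)
})

test_that("rank-sum power at a 1 SD shift with 200 per group is near 1", {
  set.seed(41)
  rej <- mean(vapply(1:200, function(i) {
    wilcoxon_rank_sum(rnorm(200), rnorm(200, 1))$p < 0.05
  }, logical(1)))
  expect_gt(rej, 0.99)
})

test_that("mutual exclusivity reconstructs the printed mutation fractions", {
  coh <- counts_cohort(384, c(F1 = 13L, F2 = 2L, F3 = 2L), flag = "CDH1",
                       flag_pos_mut = 0L, flag_neg_mut = 66L,
                       flag_neg_total = 212L)
  rep <- mutual_exclusivity_report(coh, c("F1", "F2", "F3"), "CDH1")
  expect_identical(c(rep$a, rep$b, rep$c, rep$d), c(0L, 17L, 66L, 146L))
  expect_identical(round_half_up(100 * rep$frac_mutated_fusion_neg, 1), 31.1)
  expect_equal(round(rep$chi_square$p, 3), 0.006)

  coh2 <- counts_cohort(384, c(F1 = 13L, F2 = 2L, F3 = 2L), flag = "RHOA",
                        flag_pos_mut = 0L, flag_neg_mut = 32L,
                        flag_neg_total = 212L)
  rep2 <- mutual_exclusivity_report(coh2, c("F1", "F2", "F3"), "RHOA")
  expect_identical(round_half_up(100 * rep2$frac_mutated_fusion_neg, 1), 15.1)
  expect_equal(round(rep2$chi_square$p, 2), 0.08)
  # samples with missing flags are excluded test-wise
  expect_identical(rep2$a + rep2$b + rep2$c + rep2$d, 229L)
})

test_that("association p-values are calibrated under flag independence", {
  set.seed(19)
  ps <- vapply(1:300, function(i) {
    fus <- rbinom(384, 1, 0.1) == 1
    mut <- rbinom(384, 1, 0.3) == 1
    chi_square_2x2(sum(fus & mut), sum(fus & !mut),
                   sum(!fus & mut), sum(!fus & !mut))$p
  }, numeric(1))
  ks <- suppressWarnings(ks.test(ps, "punif"))
  expect_gt(ks$p.value, 0.001)
  expect_lt(abs(mean(ps) - 0.5), 0.08)
})
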