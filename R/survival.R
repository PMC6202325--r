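# Survival analysis written from first principles: Kaplan-Meier product
# limit estimation with Greenwood/log-log confidence bands, the
# Mantel-Haenszel log-rank test, Cox proportional-hazards regression by
# Newton-Raphson on the partial likelihood (Efron or Breslow ties), and the
# Schoenfeld required-events calculation for a log-rank-powered study.

#' Kaplan-Meier estimate of the survival function
#'
#' Product-limit estimator with Greenwood variance and log-log transformed
#' pointwise 95% confidence bands. The median is the earliest time at
#' which the estimated survival drops to 0.5 or below; when the curve
#' never reaches 0.5 the median (or a confidence bound) is "not reached",
#' reported as `NA`. Median confidence limits follow the
#' Brookmeyer-Crowley construction applied to the log-log bands.
#'
#' @param time Follow-up times (>= 0).
#' @param event Logical (or 0/1) event indicators; `FALSE` = censored.
#' @param conf_level Confidence level for the bands (default 0.95).
#' @return Object of class `km_fit`: data frame `curve` (time, n_risk,
#'   n_event, n_censor, surv, std_err, lower, upper) over distinct event
#'   times, plus `median`, `median_lower`, `median_upper` (`NA` = not
#'   reached) and `n`.
#' @export
km_estimate <- function(time, event, conf_level = 0.95) {
  event <- as.logical(event)
  if (length(time) == 0L) ff_stop("km_estimate: no samples")
  if (any(time < 0)) ff_stop("negative survival time")
  ord <- order(time)
  time <- time[ord]
  event <- event[ord]
  n <- length(time)
  times <- sort(unique(time[event]))
  surv <- numeric(length(times))
  var_term <- 0
  s <- 1
  rows <- vector("list", length(times))
  for (i in seq_along(times)) {
    t_i <- times[i]
    n_risk <- sum(time >= t_i)
    d_i <- sum(time == t_i & event)
    c_i <- sum(time == t_i & !event)
    s <- s * (1 - d_i / n_risk)
    if (n_risk > d_i) var_term <- var_term + d_i / (n_risk * (n_risk - d_i))
    se <- s * sqrt(var_term)            # Greenwood
    # log-log bands: exp(-exp(log(-log S) -+ z * se(log(-log S))))
    z <- qnorm(1 - (1 - conf_level) / 2)
    if (s > 0 && s < 1) {
      se_cloglog <- sqrt(var_term) / abs(log(s))
      lower <- s^exp(z * se_cloglog)
      upper <- s^exp(-z * se_cloglog)
    } else {
      lower <- s
      upper <- s
    }
    rows[[i]] <- data.frame(time = t_i, n_risk = n_risk, n_event = d_i,
                            n_censor = c_i, surv = s, std_err = se,
                            lower = lower, upper = upper)
  }
  curve <- if (length(rows)) do.call(rbind, rows) else
    data.frame(time = numeric(), n_risk = integer(), n_event = integer(),
               n_censor = integer(), surv = numeric(), std_err = numeric(),
               lower = numeric(), upper = numeric())
  first_at_or_below <- function(col, level = 0.5) {
    hit <- which(curve[[col]] <= level + 1e-12)
    if (length(hit)) curve$time[hit[1L]] else NA_real_
  }
  structure(list(
    curve = curve, n = n,
    median = first_at_or_below("surv"),
    median_lower = first_at_or_below("lower"),
    median_upper = first_at_or_below("upper")
  ), class = "km_fit")
}

#' @export
print.km_fit <- function(x, ...) {
  fmt <- function(v) if (is.na(v)) "not reached" else format(v, digits = 4)
  cat(sprintf("<km_fit> n = %d, events = %d, median = %s [%s, %s]\n",
              x$n, sum(x$curve$n_event), fmt(x$median),
              fmt(x$median_lower), fmt(x$median_upper)))
  invisible(x)
}

#' Evaluate a Kaplan-Meier curve at given times
#' @param fit A `km_fit`.
#' @param times Times at which to evaluate S(t).
#' @return Numeric vector of survival probabilities.
#' @export
km_survival_at <- function(fit, times) {
  vapply(times, function(t) {
    idx <- which(fit$curve$time <= t)
    if (length(idx)) fit$curve$surv[max(idx)] else 1
  }, numeric(1))
}

#' Two-group Mantel-Haenszel log-rank test
#'
#' At each distinct event time the observed events in group 1 are compared
#' with the expectation under the hypergeometric null; the statistic is
#' `U^2 / V` with `U = sum(O - E)` and `V` the summed hypergeometric
#' variances, referred to a chi-square with 1 df.
#'
#' @param time,event As in [km_estimate()].
#' @param group Two-level factor/vector assigning each sample to a group.
#' @return List with `statistic`, `df`, `p`, `observed` and `expected`
#'   (per-group event counts).
#' @export
log_rank <- function(time, event, group) {
  event <- as.logical(event)
  g <- factor(group)
  if (nlevels(g) != 2L) ff_stop("log_rank requires exactly 2 groups")
  if (any(table(g) == 0L)) ff_stop("log_rank: empty group")
  if (!any(event)) ff_stop("log_rank: no events")
  times <- sort(unique(time[event]))
  U <- 0
  V <- 0
  O1 <- 0
  E1 <- 0
  g1 <- levels(g)[1L]
  for (t_i in times) {
    at_risk <- time >= t_i
    n_i <- sum(at_risk)
    n1 <- sum(at_risk & g == g1)
    d_i <- sum(time == t_i & event)
    d1 <- sum(time == t_i & event & g == g1)
    e1 <- d_i * n1 / n_i
    U <- U + (d1 - e1)
    if (n_i > 1L) {
      V <- V + d_i * (n1 / n_i) * (1 - n1 / n_i) * (n_i - d_i) / (n_i - 1)
    }
    O1 <- O1 + d1
    E1 <- E1 + e1
  }
  if (V <= 0) {
    return(list(statistic = 0, df = 1L, p = 1,
                observed = c(O1, sum(event) - O1),
                expected = c(E1, sum(event) - E1)))
  }
  stat <- U^2 / V
  list(statistic = stat, df = 1L,
       p = pchisq(stat, df = 1L, lower.tail = FALSE),
       observed = c(O1, sum(event) - O1),
       expected = c(E1, sum(event) - E1))
}

#' Cox proportional-hazards regression
#'
#' Maximises the partial likelihood by Newton-Raphson. Tied event times
#' are handled by the Efron approximation (default; less biased with the
#' heavy month-level ties typical of clinical follow-up) or the Breslow
#' approximation. Convergence is declared when the largest absolute score
#' component falls below `tol`.
#'
#' Monotone likelihood (perfect separation) is flagged by warning when a
#' coefficient diverges; results are still returned.
#'
#' @param time,event As in [km_estimate()].
#' @param covariates Numeric matrix or data frame (n x p) of covariates
#'   (logical columns are coerced to 0/1). Rows with missing values are
#'   rejected — do listwise deletion upstream.
#' @param ties `"efron"` or `"breslow"`.
#' @param tol Score convergence tolerance.
#' @param max_iter Maximum Newton iterations.
#' @return Object of class `cox_fit`: `coef`, `se`, `hr`, `ci_lower`,
#'   `ci_upper`, `wald_p` (per covariate), `loglik` (null and final),
#'   `lr_statistic`, `lr_p`, `iterations`, `converged`, `flagged_monotone`.
#' @export
cox_fit <- function(time, event, covariates, ties = c("efron", "breslow"),
                    tol = 1e-8, max_iter = 50L) {
  ties <- match.arg(ties)
  event <- as.logical(event)
  X <- as.matrix(as.data.frame(covariates))
  storage.mode(X) <- "double"
  if (anyNA(X) || anyNA(time) || anyNA(event)) {
    ff_stop("cox_fit: missing values; apply listwise deletion first")
  }
  if (!any(event)) ff_stop("cox_fit: no events")
  const <- apply(X, 2L, function(col) length(unique(col)) == 1L)
  if (any(const)) {
    ff_stop(paste0("constant covariate(s): ",
                   paste(colnames(X)[const], collapse = ", ")))
  }
  p <- ncol(X)
  beta <- rep(0, p)
  ll_null <- cox_partial_loglik(beta, time, event, X, ties)$loglik
  ll <- ll_null
  converged <- FALSE
  iter <- 0L
  for (iter in seq_len(max_iter)) {
    d <- cox_partial_loglik(beta, time, event, X, ties)
    ll <- d$loglik
    if (max(abs(d$score)) < tol) {
      converged <- TRUE
      break
    }
    step <- tryCatch(solve(d$info, d$score), error = function(e) NULL)
    if (is.null(step)) ff_stop("cox_fit: singular information matrix")
    # step-halving guard against overshoot
    new_beta <- beta + step
    new_ll <- cox_partial_loglik(new_beta, time, event, X, ties)$loglik
    halvings <- 0L
    while (is.nan(new_ll) || new_ll < ll - 1e-12) {
      step <- step / 2
      new_beta <- beta + step
      new_ll <- cox_partial_loglik(new_beta, time, event, X, ties)$loglik
      halvings <- halvings + 1L
      if (halvings > 20L) break
    }
    beta <- new_beta
  }
  d <- cox_partial_loglik(beta, time, event, X, ties)
  if (!converged && max(abs(d$score)) < 1e-4) converged <- TRUE
  flagged <- any(abs(beta) > 15)
  if (flagged) {
    warning("cox_fit: monotone partial likelihood suspected (coefficient diverging)",
            call. = FALSE)
  }
  if (!converged && !flagged) ff_stop("cox_fit: Newton-Raphson did not converge")
  se <- sqrt(diag(solve(d$info)))
  z <- beta / se
  zq <- qnorm(0.975)
  nm <- colnames(X)
  structure(list(
    coef = setNames(beta, nm), se = setNames(se, nm),
    hr = setNames(exp(beta), nm),
    ci_lower = setNames(exp(beta - zq * se), nm),
    ci_upper = setNames(exp(beta + zq * se), nm),
    wald_p = setNames(2 * pnorm(-abs(z)), nm),
    loglik = c(null = ll_null, final = d$loglik),
    lr_statistic = 2 * (d$loglik - ll_null),
    lr_p = pchisq(2 * (d$loglik - ll_null), df = p, lower.tail = FALSE),
    iterations = iter, converged = converged, flagged_monotone = flagged,
    ties = ties, n = length(time), n_event = sum(event)
  ), class = "cox_fit")
}

#' @export
print.cox_fit <- function(x, ...) {
  cat(sprintf("<cox_fit> n = %d, events = %d, ties = %s, iter = %d\n",
              x$n, x$n_event, x$ties, x$iterations))
  tab <- data.frame(coef = x$coef, HR = x$hr, lower95 = x$ci_lower,
                    upper95 = x$ci_upper, p = x$wald_p)
  print(round(tab, 4))
  invisible(x)
}

# Partial log-likelihood with score vector and information matrix.
# Subjects are swept into the risk set in order of decreasing time, so the
# risk-set sums S0, S1, S2 are running accumulators and one likelihood
# evaluation costs O(n p^2) regardless of the number of event times.
# Efron ties: within a tied event set of size d, the risk-set sum is
# progressively down-weighted by l/d of the tied subjects' contribution,
# l = 0..d-1.
cox_partial_loglik <- function(beta, time, event, X, ties) {
  n <- nrow(X)
  p <- ncol(X)
  eta <- drop(X %*% beta)
  w <- exp(eta)
  loglik <- 0
  score <- rep(0, p)
  info <- matrix(0, p, p)
  ord <- order(time, decreasing = TRUE)
  ut <- sort(unique(time[event]), decreasing = TRUE)
  dead_by_time <- split(which(event), match(time[event], ut))
  dead_by_time <- dead_by_time[as.character(seq_along(ut))]
  times <- ut
  S0 <- 0
  S1 <- rep(0, p)
  S2 <- matrix(0, p, p)
  j <- 1L
  for (k in seq_along(times)) {
    t_i <- times[k]
    while (j <= n && time[ord[j]] >= t_i) {
      i <- ord[j]
      xi <- X[i, ]
      S0 <- S0 + w[i]
      S1 <- S1 + w[i] * xi
      S2 <- S2 + w[i] * tcrossprod(xi)
      j <- j + 1L
    }
    dead <- dead_by_time[[k]]
    d <- length(dead)
    xd <- X[dead, , drop = FALSE]
    loglik <- loglik + sum(eta[dead])
    if (ties == "breslow" || d == 1L) {
      loglik <- loglik - d * log(S0)
      score <- score + colSums(xd) - d * S1 / S0
      info <- info + d * (S2 / S0 - tcrossprod(S1 / S0))
    } else {
      S0d <- sum(w[dead])
      S1d <- colSums(xd * w[dead])
      S2d <- crossprod(xd * sqrt(w[dead]))
      for (l in seq_len(d) - 1L) {
        f <- l / d
        a0 <- S0 - f * S0d
        a1 <- S1 - f * S1d
        a2 <- S2 - f * S2d
        loglik <- loglik - log(a0)
        score <- score - a1 / a0
        info <- info + a2 / a0 - tcrossprod(a1 / a0)
      }
      score <- score + colSums(xd)
    }
  }
  list(loglik = loglik, score = score, info = info)
}

#' Required number of events for a log-rank comparison
#'
#' Schoenfeld's formula for the number of events needed to detect a hazard
#' ratio `hr` between an exposed fraction `p` and the remainder at
#' two-sided level `alpha` and power `power`:
#' `d = (z[1-alpha/2] + z[power])^2 / (p (1-p) (log hr)^2)`,
#' rounded to the nearest integer.
#'
#' @param alpha Two-sided type-I error (default 0.05).
#' @param power Target power (default 0.8).
#' @param p Exposed (e.g. fusion-positive) fraction, strictly between 0
#'   and 1.
#' @param hr Hazard ratio to detect (not 1).
#' @return Integer number of events.
#' @export
required_events <- function(alpha = 0.05, power = 0.8, p, hr) {
  if (p <= 0 || p >= 1) ff_stop("exposed fraction must be in (0, 1)")
  if (hr == 1) ff_stop("required events is infinite at a hazard ratio of 1")
  z <- qnorm(1 - alpha / 2) + qnorm(power)
  d <- z^2 / (p * (1 - p) * log(hr)^2)
  as.integer(round(d))
}

#' Cohort size needed to observe a number of events
#'
#' @param events Required number of events.
#' @param event_rate Expected fraction of patients with an event during
#'   follow-up, in (0, 1].
#' @return Integer cohort size, `ceiling(events / event_rate)`.
#' @export
required_sample <- function(events, event_rate) {
  if (event_rate <= 0 || event_rate > 1) ff_stop("event rate must be in (0, 1]")
  as.integer(ceiling(events / event_rate))
}
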