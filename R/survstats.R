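#' Kaplan-Meier product-limit estimate
#'
#' Wraps [survival::survfit()] and reports the curve at the observed event
#' times, together with at-risk counts and the median survival time (smallest
#' time at which the survival estimate drops to 0.5 or below; absent if the
#' curve never reaches 0.5). Because the bracketed ranges usually quoted with
#' median follow-up are interquartile ranges, the IQR of the observed event
#' times is also reported.
#'
#' @param times Non-negative follow-up times (months).
#' @param events Logical (or 0/1) event indicators; `TRUE` = death observed.
#' @return An object of class `"km_curve"`: list with `event_times`,
#'   `survival`, `at_risk`, `n_events`, `median` (`NA` if not reached),
#'   `event_time_iqr` (length-2, `NA` if no events) and `n`.
#' @examples
#' km_estimate(c(1, 2, 3), c(TRUE, TRUE, TRUE))$median # 2
#' @export
km_estimate <- function(times, events) {
  events <- as.logical(events)
  stopifnot(length(times) == length(events), length(times) >= 1,
            all(is.finite(times)), all(times >= 0))
  fit <- survival::survfit(survival::Surv(times, events) ~ 1)
  keep <- fit$n.event > 0
  ev_t <- fit$time[keep]
  surv <- fit$surv[keep]
  at_risk <- fit$n.risk[keep]
  med <- if (any(surv <= 0.5)) ev_t[which(surv <= 0.5)[1]] else NA_real_
  iqr <- if (any(events)) {
    unname(stats::quantile(times[events], c(0.25, 0.75), type = 7))
  } else c(NA_real_, NA_real_)
  structure(list(event_times = ev_t, survival = surv, at_risk = at_risk,
                 n_events = fit$n.event[keep], median = med,
                 event_time_iqr = iqr, n = length(times)),
            class = "km_curve")
}

#' @export
print.km_curve <- function(x, ...) {
  med <- if (is.na(x$median)) "not reached" else sprintf("%.1f months", x$median)
  cat(sprintf("Kaplan-Meier curve: n = %d, %d events, median OS %s\n",
              x$n, sum(x$n_events), med))
  invisible(x)
}

#' @export
plot.km_curve <- function(x, xlab = "Months", ylab = "Survival", ...) {
  t <- c(0, rep(x$event_times, each = 2))
  s <- c(1, 1, rep(x$survival, each = 2)[-length(x$survival) * 2])
  graphics::plot(t, s, type = "l", ylim = c(0, 1), xlab = xlab, ylab = ylab, ...)
  invisible(x)
}

#' k-sample log-rank test
#'
#' Standard log-rank chi-square over the pooled risk sets, with the usual
#' hypergeometric handling of tied event times; df = k - 1. The statistic is
#' invariant under group relabeling and under strictly monotone transforms of
#' time.
#'
#' @param times Follow-up times.
#' @param events Logical event indicators.
#' @param group Group labels (k >= 2 distinct, each non-empty).
#' @return List of class `"logrank_test"`: `statistic`, `df`, `p_value`,
#'   `observed`, `expected` (per group).
#' @export
logrank_test <- function(times, events, group) {
  events <- as.logical(events)
  group <- factor(group)
  stopifnot(length(times) == length(events), length(times) == length(group))
  if (nlevels(group) < 2) stop("need at least 2 groups")
  if (any(table(group) == 0)) stop("every group must be non-empty")
  k <- nlevels(group)

  ord <- order(times)
  t <- times[ord]; e <- events[ord]; g <- as.integer(group)[ord]
  n <- length(t)

  # at-risk and event counts per group at each distinct event time
  dt <- unique(t[e])
  G <- matrix(0, n, k); G[cbind(seq_len(n), g)] <- 1
  # at risk at time s = subjects with t >= s; cumulative from the end
  cum <- apply(G[n:1, , drop = FALSE], 2, cumsum)[n:1, , drop = FALSE]
  first_idx <- match(dt, t)                 # first row with this time
  Yg <- cum[first_idx, , drop = FALSE]      # per-group at risk
  Dg <- rowsum((G * e), t)[as.character(dt), , drop = FALSE]
  Y <- rowSums(Yg); D <- rowSums(Dg)

  E <- Yg * (D / Y)
  O <- colSums(Dg)
  Eg <- colSums(E)

  # variance-covariance of (O - E), standard hypergeometric form
  V <- matrix(0, k, k)
  fac <- D * (Y - D) / pmax(Y - 1, 1) / Y
  for (i in seq_len(k)) {
    for (j in seq_len(k)) {
      pi_ <- Yg[, i] / Y
      pj <- Yg[, j] / Y
      V[i, j] <- sum(fac * pi_ * ((i == j) - pj) * Y)
    }
  }
  u <- (O - Eg)[-1]
  Vr <- V[-1, -1, drop = FALSE]
  stat <- as.numeric(t(u) %*% solve(Vr, u))
  df <- k - 1L
  structure(list(statistic = stat, df = df,
                 p_value = stats::pchisq(stat, df, lower.tail = FALSE),
                 observed = O, expected = Eg),
            class = "logrank_test")
}

#' @export
print.logrank_test <- function(x, ...) {
  cat(sprintf("Log-rank test: chi-square = %.3f on %d df, p = %.4g\n",
              x$statistic, x$df, x$p_value))
  invisible(x)
}

#' Harrell's concordance index for censored survival data
#'
#' Fraction of comparable subject pairs in which the subject with the higher
#' risk score fails earlier. A pair is comparable when the smaller of the two
#' follow-up times is an observed event; tied risk scores count 0.5.
#'
#' @param times Follow-up times.
#' @param events Logical event indicators.
#' @param risk_scores Numeric scores; higher = predicted shorter survival.
#' @return Concordance in \[0, 1\].
#' @export
harrell_c <- function(times, events, risk_scores) {
  events <- as.logical(events)
  n <- length(times)
  stopifnot(n >= 2, length(events) == n, length(risk_scores) == n,
            all(is.finite(times)), all(is.finite(risk_scores)))
  # comparable pairs (i, j): t_i < t_j and subject i had the event
  lt <- outer(times, times, "<")
  comp <- lt & events            # events recycled over columns = row index i
  n_comp <- sum(comp)
  if (n_comp == 0) stop("no comparable pairs; concordance undefined")
  gt <- outer(risk_scores, risk_scores, ">")
  eq <- outer(risk_scores, risk_scores, "==")
  (sum(comp & gt) + 0.5 * sum(comp & eq)) / n_comp
}

#' Univariate Cox proportional-hazards regression
#'
#' Newton-Raphson maximization of the Breslow partial likelihood for a single
#' covariate, with a Wald 95% confidence interval on the hazard ratio.
#'
#' @param times Follow-up times.
#' @param events Logical event indicators.
#' @param x Numeric covariate (must not be constant).
#' @param max_iter,tol Newton-Raphson controls.
#' @return List of class `"cox_uni"`: `coef` (log hazard ratio), `hr`, `se`,
#'   `ci` (length-2, 95%), `p_value`, `iterations`.
#' @export
cox_univariate <- function(times, events, x, max_iter = 30L, tol = 1e-9) {
  events <- as.logical(events)
  n <- length(times)
  stopifnot(length(events) == n, length(x) == n, all(is.finite(x)))
  if (stats::sd(x) == 0) stop("degenerate covariate: x is constant")
  if (!any(events)) stop("no events observed")

  ord <- order(times)
  t <- times[ord]; e <- events[ord]; xx <- x[ord]
  dt <- unique(t[e])
  first_idx <- match(dt, t)
  d_per <- as.numeric(rowsum(as.numeric(e), t)[as.character(dt), ])
  sx_per <- as.numeric(rowsum(xx * e, t)[as.character(dt), ])

  # risk-set sums, cumulated from the largest time down
  sums <- function(beta) {
    w <- exp(beta * xx)
    list(S0 = rev(cumsum(rev(w)))[first_idx],
         S1 = rev(cumsum(rev(w * xx)))[first_idx],
         S2 = rev(cumsum(rev(w * xx^2)))[first_idx])
  }
  loglik <- function(beta) sum(sx_per * beta) - sum(d_per * log(sums(beta)$S0))

  beta <- 0
  ll <- loglik(beta)
  for (it in seq_len(max_iter)) {
    s <- sums(beta)
    U <- sum(sx_per - d_per * s$S1 / s$S0)
    I <- sum(d_per * (s$S2 / s$S0 - (s$S1 / s$S0)^2))
    if (!is.finite(I) || I <= 0) {
      stop("information matrix not positive; last beta = ", beta)
    }
    step <- U / I
    # halve the step until the partial likelihood improves (guards against
    # overshoot with near-monotone likelihoods)
    ll_new <- loglik(beta + step)
    halvings <- 0L
    while ((!is.finite(ll_new) || ll_new < ll) && halvings < 20L) {
      step <- step / 2
      ll_new <- loglik(beta + step)
      halvings <- halvings + 1L
    }
    beta <- beta + step
    ll <- ll_new
    if (abs(step) < tol) break
  }
  if (abs(step) >= tol) {
    stop(sprintf("Cox fit did not converge in %d iterations; last beta = %.6f",
                 max_iter, beta))
  }
  se <- sqrt(1 / I)
  z <- beta / se
  structure(list(coef = beta, hr = exp(beta), se = se,
                 ci = exp(beta + c(-1, 1) * stats::qnorm(0.975) * se),
                 p_value = 2 * stats::pnorm(-abs(z)), iterations = it),
            class = "cox_uni")
}

#' @export
print.cox_uni <- function(x, ...) {
  cat(sprintf("Univariate Cox: HR %.3f [95%% CI %.3f-%.3f], p = %.4g\n",
              x$hr, x$ci[1], x$ci[2], x$p_value))
  invisible(x)
}

#' Odds ratio from a 2x2 table
#'
#' Cross-product odds ratio with the Haldane-Anscombe 0.5 continuity
#' correction when any cell is zero, and a Woolf (log-scale normal) 95%
#' confidence interval. A zero row or column makes the estimate unstable and
#' is flagged.
#'
#' @param table 2x2 matrix of non-negative integer counts; rows = exposure,
#'   columns = outcome.
#' @return List of class `"odds_ratio"`: `or`, `log_or`, `se`, `ci`,
#'   `corrected` (logical), `unstable` (logical).
#' @examples
#' odds_ratio(matrix(c(20, 5, 5, 20), 2, byrow = TRUE))$or # 16
#' @export
odds_ratio <- function(table) {
  table <- as.matrix(table)
  stopifnot(all(dim(table) == c(2, 2)), all(table >= 0),
            all(table == round(table)))
  unstable <- any(rowSums(table) == 0) || any(colSums(table) == 0)
  corrected <- any(table == 0)
  tt <- if (corrected) table + 0.5 else table
  lor <- log(tt[1, 1]) + log(tt[2, 2]) - log(tt[1, 2]) - log(tt[2, 1])
  se <- sqrt(sum(1 / tt))
  structure(list(or = exp(lor), log_or = lor, se = se,
                 ci = exp(lor + c(-1, 1) * stats::qnorm(0.975) * se),
                 corrected = corrected, unstable = unstable),
            class = "odds_ratio")
}

#' @export
print.odds_ratio <- function(x, ...) {
  cat(sprintf("OR %.2f [95%% CI %.2f-%.2f]%s\n", x$or, x$ci[1], x$ci[2],
              if (x$unstable) " (unstable: empty row/column)" else ""))
  invisible(x)
}
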