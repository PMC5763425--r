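# Univariate Cox proportional-hazards fitting.
#
# The screening stages fit the same survival outcome against tens of
# thousands of covariates one at a time, so the risk-set bookkeeping (sort
# order, risk-set cutoffs, tied-death groups, Efron weights) is computed
# once per clinical table by cox_prep() and reused across covariates.

# Precompute everything about (time, event) that the partial likelihood
# needs. Subjects are sorted by decreasing time so cumulative sums give
# risk-set totals; censored subjects tied with a death stay in that risk set.
cox_prep <- function(time, event) {
  n <- length(time)
  ord <- order(time, decreasing = TRUE)
  ts <- time[ord]
  es <- event[ord]
  dpos <- which(es == 1)              # sorted positions of deaths (time desc)
  dtimes <- unique(ts[dpos])          # death times, decreasing
  # risk-set cutoff per death time: last sorted position with time >= t
  mpos <- vapply(dtimes, function(t) max(which(ts == t)), integer(1))
  gd <- match(ts[dpos], dtimes)       # death -> death-time group
  dcount <- as.integer(table(factor(gd, levels = seq_along(dtimes))))
  gend <- cumsum(dcount)              # last index of each group within dpos
  # Efron weights l/d expanded over (group, l = 0..d-1)
  jl <- rep(seq_along(dtimes), dcount)
  wl <- unlist(lapply(dcount, function(d) (seq_len(d) - 1) / d), use.names = FALSE)
  list(n = n, ord = ord, dpos = dpos, mpos = mpos,
       gend = gend, jl = jl, wl = wl, n_events = length(dpos))
}

# Efron log partial likelihood with first two derivatives at beta, for a
# covariate already sorted by decreasing time.
cox_lik <- function(beta, xs, prep) {
  r <- exp(beta * xs)
  rx <- r * xs
  rxx <- rx * xs
  S0 <- cumsum(r)[prep$mpos]
  S1 <- cumsum(rx)[prep$mpos]
  S2 <- cumsum(rxx)[prep$mpos]
  rd <- r[prep$dpos]
  xd <- xs[prep$dpos]
  gsum <- function(v) diff(c(0, cumsum(v)[prep$gend]))
  D0 <- gsum(rd)
  D1 <- gsum(rd * xd)
  D2 <- gsum(rd * xd * xd)
  denom <- S0[prep$jl] - prep$wl * D0[prep$jl]
  num1 <- S1[prep$jl] - prep$wl * D1[prep$jl]
  num2 <- S2[prep$jl] - prep$wl * D2[prep$jl]
  m1 <- num1 / denom
  list(loglik = beta * sum(xd) - sum(log(denom)),
       score = sum(xd) - sum(m1),
       info = sum(num2 / denom - m1 * m1))
}

# Newton with step-halving on the standardized covariate. Monotone
# likelihood (perfectly separating covariate) drives |beta| off to infinity;
# it is detected by the standardized coefficient passing a large bound and
# flagged through converged = FALSE.
cox_newton <- function(xs, prep, tol = 1e-9, max_iter = 50L) {
  beta <- 0
  ll <- cox_lik(beta, xs, prep)
  converged <- FALSE
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    if (ll$info <= 0) break
    delta <- ll$score / ll$info
    step <- delta
    new <- cox_lik(beta + step, xs, prep)
    halvings <- 0L
    while ((!is.finite(new$loglik) || new$loglik < ll$loglik) && halvings < 20L) {
      step <- step / 2
      new <- cox_lik(beta + step, xs, prep)
      halvings <- halvings + 1L
    }
    beta <- beta + step
    ll <- new
    if (abs(beta) > 30) break  # monotone likelihood on a standardized scale
    if (abs(delta) < tol) { converged <- TRUE; break }
  }
  list(beta = beta, info = ll$info, loglik = ll$loglik,
       converged = converged, iterations = iter)
}

#' Univariate Cox proportional-hazards regression
#'
#' Fits the Cox model with a single covariate by Newton maximization of the
#' partial likelihood with Efron's approximation for tied death times
#' (step-halving, tolerance 1e-9 on the update, at most 50 iterations). The
#' p-value is the two-sided Wald test of coefficient zero. A monotone
#' partial likelihood (covariate perfectly separating events) is flagged via
#' \code{converged = FALSE} rather than returning silently.
#'
#' @param x Covariate vector (e.g. per-sample beta values of one site).
#' @param time Follow-up time in days, positive.
#' @param event Event indicator: 1 = death observed, 0 = censored.
#' @return Object of class \code{cox_fit}: coefficient (log hazard per unit
#'   covariate), standard_error, p_value, converged, loglik, n, n_events,
#'   iterations.
#' @export
cox_univariate <- function(x, time, event) {
  n <- length(x)
  if (length(time) != n || length(event) != n) stopf("x, time, event must have equal length")
  if (any(!is.finite(x))) stopf("non-finite covariate values")
  prep <- cox_prep(time, event)
  if (prep$n_events < 2) stopf("need at least 2 observed events, got %d", prep$n_events)
  sdx <- stats::sd(x)
  if (sdx == 0) stopf("constant covariate: Cox coefficient undefined")
  xs <- (x[prep$ord] - mean(x)) / sdx
  fit <- cox_newton(xs, prep)
  se_std <- if (fit$info > 0) 1 / sqrt(fit$info) else NA_real_
  coefficient <- fit$beta / sdx
  standard_error <- se_std / sdx
  z <- fit$beta / se_std
  structure(list(coefficient = coefficient,
                 standard_error = standard_error,
                 p_value = 2 * stats::pnorm(-abs(z)),
                 converged = fit$converged,
                 loglik = fit$loglik,
                 n = n,
                 n_events = prep$n_events,
                 iterations = fit$iterations),
            class = "cox_fit")
}

#' @export
print.cox_fit <- function(x, ...) {
  cat(sprintf("Univariate Cox fit (n = %d, events = %d)\n", x$n, x$n_events))
  cat(sprintf("  coef %.4f  (se %.4f)  HR %.3f  Wald p %.3g%s\n",
              x$coefficient, x$standard_error, exp(x$coefficient), x$p_value,
              if (!x$converged) "  [did not converge]" else ""))
  invisible(x)
}

# Fast path used by the screening stages: fit every row of `m` against the
# same outcome, reusing one cox_prep. Rows that fail (constant covariate,
# non-finite fit) yield NA and are counted by the caller.
cox_screen_matrix <- function(m, time, event) {
  prep <- cox_prep(time, event)
  if (prep$n_events < 2) stopf("need at least 2 observed events, got %d", prep$n_events)
  nr <- nrow(m)
  coefficient <- p_value <- se <- rep(NA_real_, nr)
  converged <- rep(FALSE, nr)
  for (i in seq_len(nr)) {
    x <- m[i, ]
    sdx <- stats::sd(x)
    if (sdx == 0 || !is.finite(sdx)) next
    xs <- (x[prep$ord] - mean(x)) / sdx
    fit <- cox_newton(xs, prep)
    if (fit$info <= 0) next
    se_std <- 1 / sqrt(fit$info)
    coefficient[i] <- fit$beta / sdx
    se[i] <- se_std / sdx
    p_value[i] <- 2 * stats::pnorm(-abs(fit$beta / se_std))
    converged[i] <- fit$converged
  }
  data.frame(site = rownames(m), coefficient = coefficient,
             standard_error = se, p_value = p_value,
             converged = converged, stringsAsFactors = FALSE)
}

#' Two-group log-rank test
#'
#' Standard 1-df log-rank chi-square comparing the survival experience of
#' two groups (computed through \code{survival::survdiff}).
#'
#' @param time_a,event_a Times and event indicators for group A.
#' @param time_b,event_b Times and event indicators for group B.
#' @return Object of class \code{logrank_result}: chi_square, p_value, and
#'   per-group observed/expected event counts.
#' @export
logrank_test <- function(time_a, event_a, time_b, event_b) {
  if (length(time_a) == 0 || length(time_b) == 0) stopf("both groups must be non-empty")
  if (sum(event_a) + sum(event_b) < 1) stopf("need at least one observed event")
  time <- c(time_a, time_b)
  event <- c(event_a, event_b)
  grp <- rep(c("A", "B"), c(length(time_a), length(time_b)))
  sd <- survival::survdiff(survival::Surv(time, event) ~ grp)
  structure(list(chi_square = unname(sd$chisq),
                 p_value = stats::pchisq(sd$chisq, df = 1, lower.tail = FALSE),
                 observed = unname(sd$obs),
                 expected = unname(sd$exp)),
            class = "logrank_result")
}

#' @export
print.logrank_result <- function(x, ...) {
  cat(sprintf("Log-rank test: chi-square %.3f (1 df), p = %.3g\n",
              x$chi_square, x$p_value))
  invisible(x)
}

#' Hazard ratio between two groups
#'
#' HR and 95\% confidence interval from a univariate Cox fit on the 0/1
#' group indicator; the interval is the normal approximation on the log
#' scale, exp(coef +/- 1.96 se).
#'
#' @param group Binary group labels (0/1, logical, or a 2-level factor);
#'   the hazard ratio is for group 1 relative to group 0.
#' @param time,event Survival outcome as in [cox_univariate()].
#' @return Object of class \code{hazard_ratio}: hr, ci_low, ci_high,
#'   coefficient, standard_error, p_value.
#' @export
hazard_ratio <- function(group, time, event) {
  if (is.factor(group)) group <- as.integer(group) - 1L
  group <- as.numeric(group)
  if (!all(group %in% c(0, 1))) stopf("`group` must be binary (0/1)")
  if (sum(group == 0) < 1 || sum(group == 1) < 1) stopf("both groups must be non-empty")
  fit <- cox_univariate(group, time, event)
  structure(list(hr = exp(fit$coefficient),
                 ci_low = exp(fit$coefficient - 1.96 * fit$standard_error),
                 ci_high = exp(fit$coefficient + 1.96 * fit$standard_error),
                 coefficient = fit$coefficient,
                 standard_error = fit$standard_error,
                 p_value = fit$p_value,
                 converged = fit$converged),
            class = "hazard_ratio")
}

#' @export
print.hazard_ratio <- function(x, ...) {
  cat(sprintf("HR %.3f (95%% CI %.3f-%.3f), Wald p = %.3g\n",
              x$hr, x$ci_low, x$ci_high, x$p_value))
  invisible(x)
}

#' Kaplan-Meier survival estimate
#'
#' Product-limit estimate of the survival function (through
#' \code{survival::survfit}), returned as a step function starting at
#' S(0) = 1.
#'
#' @param time,event Survival outcome.
#' @return Object of class \code{km_curve}: data.frame with columns time,
#'   survival, n_risk, n_event.
#' @export
km_estimate <- function(time, event) {
  if (length(time) == 0) stopf("empty input")
  sf <- survival::survfit(survival::Surv(time, event) ~ 1)
  df <- data.frame(time = c(0, sf$time),
                   survival = c(1, sf$surv),
                   n_risk = c(length(time), sf$n.risk),
                   n_event = c(0, sf$n.event))
  class(df) <- c("km_curve", "data.frame")
  df
}

#' @export
plot.km_curve <- function(x, ..., xlab = "Days", ylab = "Survival probability") {
  plot(x$time, x$survival, type = "s", ylim = c(0, 1), xlab = xlab, ylab = ylab, ...)
  invisible(x)
}
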