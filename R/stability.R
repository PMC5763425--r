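#' Hypergeometric overlap tail probability
#'
#' Probability of observing an overlap of at least \code{x} members between
#' a set of size K and a set of size N drawn from a universe of size M:
#' p = 1 - sum over i < x of C(K,i) C(M-K,N-i) / C(M,N), evaluated as the
#' complementary sum over i >= x so small tails are not lost to
#' cancellation. Terms are accumulated from log-gamma binomial
#' coefficients, so large universes do not overflow.
#'
#' @param x Observed overlap count, 0 <= x <= min(K, N).
#' @param K,N Sizes of the two selected sets.
#' @param M Universe size (number of features both selections drew from).
#' @return The tail probability in \[0, 1\]; x = 0 gives exactly 1.
#' @export
hypergeometric_overlap_p <- function(x, K, N, M) {
  vals <- c(x = x, K = K, N = N, M = M)
  if (any(vals != round(vals)) || any(vals < 0)) stopf("x, K, N, M must be non-negative integers")
  if (K > M || N > M) stopf("K and N must not exceed the universe size M")
  if (x > min(K, N)) stopf("overlap x = %d exceeds min(K, N) = %d", x, min(K, N))
  if (x == 0) return(1)
  i <- x:min(K, N)
  logp <- lchoose(K, i) + lchoose(M - K, N - i) - lchoose(M, N)
  p <- sum(exp(logp))
  max(0, min(1, p))
}

#' Split-half prognostic feature selection
#'
#' One replicate of the stability experiment: the samples are randomly
#' divided into two equal halves, each half is screened feature-by-feature
#' with univariate Cox regression at p < alpha, and the significance of the
#' overlap between the two selected feature sets is assessed with the
#' hypergeometric test over the universe of all features screened.
#'
#' @param m Feature-by-sample matrix (any platform: methylation beta
#'   values, expression, miRNA).
#' @param clinical Clinical table aligned with \code{m} internally.
#' @param alpha Per-feature screening threshold (default 0.05).
#' @param seed Integer seed for the half split.
#' @return list(set_a, set_b, overlap = list(x, K, N, M), p_value).
#' @export
half_split_selection <- function(m, clinical, alpha = 0.05, seed = 1) {
  assert_methylation_matrix(m)
  al <- align_samples(m, clinical)
  cl <- al$clinical
  n <- nrow(cl)
  if (n < 4) stopf("need at least 4 samples, got %d", n)
  halves <- split_train_test(cl$sample, seed)
  sel <- lapply(halves, function(ids) {
    sub <- cl[match(ids, cl$sample), ]
    if (sum(sub$event) < 2)
      stopf("a half split has fewer than 2 observed events; cannot screen")
    res <- cox_screen_matrix(al$m[, ids, drop = FALSE], sub$time_days, sub$event)
    res$site[!is.na(res$p_value) & res$p_value < alpha]
  })
  x <- length(intersect(sel$train, sel$test))
  K <- length(sel$train)
  N <- length(sel$test)
  M <- nrow(m)
  list(set_a = sel$train, set_b = sel$test,
       overlap = list(x = x, K = K, N = N, M = M),
       p_value = hypergeometric_overlap_p(x, K, N, M))
}

#' Split-half stability of prognostic feature selection
#'
#' Repeats [half_split_selection()] B times (replicate r uses seed
#' \code{seed + r}, a documented counter scheme that makes the whole report
#' reproducible) and collects one hypergeometric overlap p-value per
#' replicate. Platforms whose survival-associated features are selected
#' reproducibly across random halves yield small p-values.
#'
#' @param m,clinical As in [half_split_selection()].
#' @param B Number of replicates (default 100).
#' @param alpha Per-feature screening threshold.
#' @param seed Master seed.
#' @param platform Free-text label stored in the report.
#' @return Object of class \code{stability_report}: platform, table
#'   (replicate, x, K, N, M, p_value), B, alpha, seed.
#' @export
run_stability <- function(m, clinical, B = 100, alpha = 0.05, seed = 1,
                          platform = "platform") {
  if (B < 1) stopf("B must be >= 1")
  rows <- vector("list", B)
  for (r in seq_len(B)) {
    hs <- half_split_selection(m, clinical, alpha = alpha, seed = seed + r)
    rows[[r]] <- data.frame(replicate = r, x = hs$overlap$x, K = hs$overlap$K,
                            N = hs$overlap$N, M = hs$overlap$M,
                            p_value = hs$p_value)
  }
  structure(list(platform = platform,
                 table = do.call(rbind, rows),
                 B = as.integer(B),
                 alpha = alpha,
                 seed = as.integer(seed)),
            class = "stability_report")
}

#' @export
print.stability_report <- function(x, ...) {
  cat(sprintf("Split-half stability report [%s]: B = %d replicates, alpha = %g\n",
              x$platform, x$B, x$alpha))
  cat(sprintf("  overlap p-values: median %.3g, %d of %d below 0.05\n",
              stats::median(x$table$p_value), sum(x$table$p_value < 0.05), x$B))
  invisible(x)
}

#' Compare stability p-values between two platforms
#'
#' Two-sided Wilcoxon rank-sum test on the replicate overlap p-values of
#' two platforms; a small p-value means the platforms differ in how
#' reproducibly they select prognostic features. The exact null
#' distribution is used for small tie-free samples; otherwise the normal
#' approximation with tie and continuity correction.
#'
#' @param p_a,p_b Replicate p-value vectors, e.g. \code{report$table$p_value}
#'   from [run_stability()].
#' @return The Wilcoxon rank-sum p-value.
#' @export
compare_platforms <- function(p_a, p_b) {
  if (length(p_a) == 0 || length(p_b) == 0) stopf("both p-value vectors must be non-empty")
  suppressWarnings(stats::wilcox.test(p_a, p_b, correct = TRUE)$p.value)
}
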