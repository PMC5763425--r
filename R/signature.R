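#' Random half split into training and test samples
#'
#' Reproducible shuffle of the sample ids into disjoint halves of sizes
#' ceiling(n/2) (training) and floor(n/2) (test).
#'
#' @param sample_ids Character vector of sample ids (n >= 4).
#' @param seed Integer seed; the same seed always gives the same split.
#' @return list(train, test) of sample ids.
#' @export
split_train_test <- function(sample_ids, seed) {
  n <- length(sample_ids)
  if (n < 4) stopf("need at least 4 samples to split, got %d", n)
  shuffled <- with_seed(seed, sample(sample_ids))
  n_train <- ceiling(n / 2)
  list(train = shuffled[seq_len(n_train)],
       test = shuffled[(n_train + 1):n])
}

new_signature <- function(entries, alpha, training_samples, source) {
  entries <- entries[order(entries$p_value, entries$site), , drop = FALSE]
  rownames(entries) <- NULL
  structure(list(entries = entries,
                 positive_sites = entries$site[entries$coefficient >= 0],
                 negative_sites = entries$site[entries$coefficient < 0],
                 alpha = alpha,
                 training_samples = training_samples,
                 source = source),
            class = "prognostic_signature")
}

#' Screen hub sites for survival association
#'
#' Fits a univariate Cox model per hub site (methylation level as the
#' covariate, overall survival as the outcome) and retains sites with Wald
#' p below \code{alpha}. The raw p-value cut is used without
#' multiple-testing correction — the screen is a candidate filter, not an
#' inference procedure. Per-site fit failures (e.g. constant sites) are
#' skipped with a warning.
#'
#' @param m Methylation matrix.
#' @param clinical Clinical table; samples are aligned with \code{m}
#'   internally.
#' @param hubs A \code{hub_set} from [select_hubs()], or a character vector
#'   of site ids; must be a subset of the matrix sites.
#' @param alpha Significance threshold (default 0.05).
#' @return Object of class \code{prognostic_signature}: entries (site,
#'   coefficient, p_value, sorted by p), positive_sites (risk-increasing,
#'   coefficient > 0), negative_sites (protective), plus the alpha and
#'   training sample ids used.
#' @export
screen_hubs <- function(m, clinical, hubs, alpha = 0.05) {
  sites <- if (inherits(hubs, "hub_set")) hubs$sites else as.character(hubs)
  missing <- setdiff(sites, rownames(m))
  if (length(missing) > 0)
    stopf("%d hub site(s) absent from the matrix (e.g. %s)", length(missing), missing[1])
  al <- align_samples(m, clinical)
  res <- cox_screen_matrix(al$m[sites, , drop = FALSE],
                           al$clinical$time_days, al$clinical$event)
  failed <- is.na(res$p_value)
  if (any(failed)) warnf("skipped %d site(s) whose Cox fit failed", sum(failed))
  keep <- !failed & res$p_value < alpha
  new_signature(res[keep, c("site", "coefficient", "p_value"), drop = FALSE],
                alpha = alpha,
                training_samples = al$clinical$sample,
                source = "hub_screen")
}

#' @export
print.prognostic_signature <- function(x, ...) {
  cat(sprintf("Prognostic signature: %d sites (%d risk-increasing, %d protective)\n",
              nrow(x$entries), length(x$positive_sites), length(x$negative_sites)))
  if (!is.na(x$alpha)) cat(sprintf("  Cox screen at p < %g on %d training samples\n",
                                   x$alpha, length(x$training_samples)))
  if (nrow(x$entries) > 0) {
    cat("  top sites:\n")
    print(utils::head(x$entries, 5), row.names = FALSE)
  }
  invisible(x)
}

#' GGI-style prognosis risk scores
#'
#' Per sample, the risk score is the sum of methylation levels over
#' signature sites with positive Cox coefficient minus the sum over sites
#' with negative coefficient: high methylation at risk-increasing sites and
#' low methylation at protective sites both raise the score.
#'
#' @param signature A \code{prognostic_signature}.
#' @param m Methylation matrix containing every signature site.
#' @return data.frame (sample, score) of class \code{risk_scores}.
#' @export
compute_risk_scores <- function(signature, m) {
  assert_methylation_matrix(m)
  sites <- signature$entries$site
  missing <- setdiff(sites, rownames(m))
  if (length(missing) > 0)
    stopf("signature sites absent from matrix: %s",
          paste(utils::head(missing, 10), collapse = ", "))
  pos <- signature$positive_sites
  neg <- signature$negative_sites
  score <- rep(0, ncol(m))
  if (length(pos) > 0) score <- score + colSums(m[pos, , drop = FALSE])
  if (length(neg) > 0) score <- score - colSums(m[neg, , drop = FALSE])
  df <- data.frame(sample = colnames(m), score = unname(score),
                   stringsAsFactors = FALSE)
  class(df) <- c("risk_scores", "data.frame")
  df
}

#' Stratify samples into bad- and good-outcome groups
#'
#' The floor(n/2) samples with the highest risk scores form the
#' bad-outcome group ("top 50 percent"); the rest are the good-outcome
#' group. Score ties at the boundary are broken deterministically by sample
#' id, so repeated runs give identical groups.
#'
#' @param scores A \code{risk_scores} data.frame from
#'   [compute_risk_scores()].
#' @return The same data.frame with a \code{group} factor column
#'   (levels bad, good).
#' @export
stratify <- function(scores) {
  n <- nrow(scores)
  if (n < 2) stopf("need at least 2 samples to stratify, got %d", n)
  n_bad <- floor(n / 2)
  ord <- order(-scores$score, scores$sample)
  group <- rep("good", n)
  group[ord[seq_len(n_bad)]] <- "bad"
  scores$group <- factor(group, levels = c("bad", "good"))
  scores
}

#' Evaluate a prognostic signature on a cohort
#'
#' Scores every sample, splits the cohort at the risk-score median into
#' bad- and good-outcome halves, and compares their survival with the
#' log-rank test and the bad-vs-good hazard ratio.
#'
#' @param signature A \code{prognostic_signature}.
#' @param m Methylation matrix for the cohort to evaluate.
#' @param clinical Clinical table (aligned internally).
#' @param label Free-text dataset label, e.g. "train" or "test". Evaluation
#'   on the cohort the signature was screened on is optimistic; report it
#'   as such.
#' @return Object of class \code{signature_evaluation}: label, n, logrank
#'   ([logrank_test()] result), hr ([hazard_ratio()] result, bad relative
#'   to good), the per-sample stratified scores, and KM curves per group.
#' @export
evaluate_signature <- function(signature, m, clinical, label = "data") {
  al <- align_samples(m, clinical)
  scored <- stratify(compute_risk_scores(signature, al$m))
  cl <- al$clinical
  bad <- scored$group == "bad"
  lr <- logrank_test(cl$time_days[bad], cl$event[bad],
                     cl$time_days[!bad], cl$event[!bad])
  hr <- hazard_ratio(as.integer(bad), cl$time_days, cl$event)
  structure(list(label = label,
                 n = nrow(cl),
                 logrank = lr,
                 hr = hr,
                 scores = scored,
                 km = list(bad = km_estimate(cl$time_days[bad], cl$event[bad]),
                           good = km_estimate(cl$time_days[!bad], cl$event[!bad]))),
            class = "signature_evaluation")
}

#' @export
print.signature_evaluation <- function(x, ...) {
  cat(sprintf("Signature evaluation [%s], n = %d\n", x$label, x$n))
  cat("  "); print(x$logrank)
  cat("  bad vs good outcome: "); print(x$hr)
  invisible(x)
}

#' @export
plot.signature_evaluation <- function(x, ...,
                                      col = c(bad = "firebrick", good = "forestgreen")) {
  plot(x$km$bad$time, x$km$bad$survival, type = "s", col = col[["bad"]],
       ylim = c(0, 1), xlab = "Days", ylab = "Survival probability",
       main = sprintf("Risk-score stratification (%s)", x$label), ...)
  lines(x$km$good$time, x$km$good$survival, type = "s", col = col[["good"]])
  legend("bottomleft", legend = c("bad outcome", "good outcome"),
         col = col, lty = 1, bty = "n")
  invisible(x)
}

#' Genome-wide control signature
#'
#' The comparison baseline for the hub-filtered signature: univariate Cox
#' fits over every site in the matrix (not just hubs), keeping the
#' \code{size} sites with the smallest p-values, with their signed
#' coefficients.
#'
#' @param m Methylation matrix.
#' @param clinical Clinical table (aligned internally).
#' @param size Number of sites to keep (<= number of sites).
#' @return A \code{prognostic_signature} of exactly \code{size} sites.
#' @export
control_signature <- function(m, clinical, size) {
  assert_methylation_matrix(m)
  if (size > nrow(m)) stopf("size (%d) exceeds site count (%d)", size, nrow(m))
  if (size < 1) stopf("size must be >= 1")
  al <- align_samples(m, clinical)
  res <- cox_screen_matrix(al$m, al$clinical$time_days, al$clinical$event)
  res <- res[!is.na(res$p_value), , drop = FALSE]
  if (nrow(res) < size) stopf("only %d sites had a successful Cox fit (< size = %d)", nrow(res), size)
  res <- res[order(res$p_value, res$site), , drop = FALSE]
  new_signature(res[seq_len(size), c("site", "coefficient", "p_value"), drop = FALSE],
                alpha = NA_real_,
                training_samples = al$clinical$sample,
                source = "genome_wide_control")
}
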