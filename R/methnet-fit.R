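#' Fit a hub-based prognostic methylation signature
#'
#' The core estimator of the package, run on a training cohort in four
#' stages: (1) build the rank-based co-methylation network (each site keeps
#' its k most correlated partners by absolute Spearman rho), (2) fit a
#' power law to the degree distribution as a scale-free diagnostic,
#' (3) select the top \code{hub_fraction} of sites by degree as hubs, and
#' (4) screen the hubs with univariate Cox regression at p < alpha to
#' obtain the prognostic signature. The fitted object predicts GGI-style
#' risk scores (sum of beta values over risk-increasing signature sites
#' minus the sum over protective ones) for new cohorts.
#'
#' @param m Methylation matrix (sites x samples, beta values in \[0, 1\]).
#' @param clinical Clinical table (sample, time_days, event); samples are
#'   aligned with \code{m} internally.
#' @param k Neighbors per site in the network (default 10).
#' @param hub_fraction Fraction of sites kept as hubs (default 0.10).
#' @param alpha Cox screening threshold (default 0.05).
#' @param chunk_size Passed to [build_rank_network()].
#' @return Object of class \code{methnet_fit}: network, powerlaw, hubs,
#'   signature, and the aligned training data dimensions.
#' @seealso [predict.methnet_fit()], [evaluate_signature()]
#' @examples
#' cfg <- synth_config(n_sites = 120, n_samples = 60, n_modules = 4,
#'                     module_size = 20, n_drivers = 8, seed = 7)
#' gen <- generate_methylation(cfg)
#' clin <- generate_survival(gen$m, gen$truth, cfg)
#' fit <- methnet_fit(gen$m, clin, k = 5)
#' fit
#' head(predict(fit, gen$m))
#' @export
methnet_fit <- function(m, clinical, k = 10, hub_fraction = 0.10,
                        alpha = 0.05, chunk_size = 512L) {
  al <- align_samples(m, clinical)
  network <- build_rank_network(al$m, k = k, chunk_size = chunk_size)
  dist <- degree_distribution(network)
  powerlaw <- tryCatch(fit_power_law(dist), error = function(e) NULL)
  hubs <- select_hubs(network, fraction = hub_fraction)
  signature <- screen_hubs(al$m, al$clinical, hubs, alpha = alpha)
  structure(list(network = network,
                 degree_distribution = dist,
                 powerlaw = powerlaw,
                 hubs = hubs,
                 signature = signature,
                 k = k, hub_fraction = hub_fraction, alpha = alpha,
                 n_sites = nrow(al$m), n_samples = ncol(al$m),
                 training_samples = al$clinical$sample),
            class = "methnet_fit")
}

#' @export
print.methnet_fit <- function(x, ...) {
  cat("Hub-based prognostic methylation signature fit\n")
  cat(sprintf("  training data: %d sites x %d samples\n", x$n_sites, x$n_samples))
  cat(sprintf("  network: k = %d, %d selection pairs, %d unique edges\n",
              x$k, nrow(x$network$selection_pairs), nrow(x$network$edges)))
  cat(sprintf("  hubs: %d sites with degree >= %d (top %.3g by degree)\n",
              length(x$hubs$sites), x$hubs$degree_threshold, x$hub_fraction))
  cat(sprintf("  signature: %d sites at Cox p < %g (%d risk-increasing, %d protective)\n",
              nrow(x$signature$entries), x$alpha,
              length(x$signature$positive_sites), length(x$signature$negative_sites)))
  invisible(x)
}

#' @export
summary.methnet_fit <- function(object, ...) {
  print(object)
  if (!is.null(object$powerlaw)) { cat("\n"); print(object$powerlaw) }
  cat("\n"); print(object$signature)
  invisible(object)
}

#' Extract signature coefficients
#'
#' @param object A \code{methnet_fit}.
#' @param ... Unused.
#' @return Named numeric vector of signed Cox coefficients over the
#'   signature sites.
#' @export
coef.methnet_fit <- function(object, ...) {
  stats::setNames(object$signature$entries$coefficient,
                  object$signature$entries$site)
}

#' Predict risk scores or outcome groups for a new cohort
#'
#' @param object A \code{methnet_fit}.
#' @param newdata Methylation matrix containing all signature sites.
#' @param type \code{"score"} for the per-sample risk-score table,
#'   \code{"group"} for the median-split bad/good stratification.
#' @param ... Unused.
#' @return A \code{risk_scores} data.frame (with a \code{group} column when
#'   \code{type = "group"}).
#' @export
predict.methnet_fit <- function(object, newdata, type = c("score", "group"), ...) {
  type <- match.arg(type)
  scores <- compute_risk_scores(object$signature, newdata)
  if (type == "group") scores <- stratify(scores)
  scores
}

#' Plot the degree distribution and its power-law fit
#'
#' Log-log scatter of (degree, node count) with the fitted line; a
#' straight-line fit diagnoses scale-free topology.
#'
#' @param x A \code{methnet_fit}.
#' @param ... Passed to \code{plot}.
#' @export
plot.methnet_fit <- function(x, ...) {
  d <- x$degree_distribution
  d <- d[d$degree > 0 & d$count > 0, ]
  plot(d$degree, d$count, log = "xy", xlab = "Degree", ylab = "Node count",
       main = "Degree distribution", ...)
  if (!is.null(x$powerlaw))
    graphics::lines(d$degree,
                    10^x$powerlaw$intercept * d$degree^x$powerlaw$exponent,
                    col = "firebrick")
  invisible(x)
}
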