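#' Run the end-to-end prognosis pipeline
#'
#' Orchestrates the whole analysis on one cohort and writes every artifact
#' to \code{output_dir}: network edge list, degree distribution and
#' power-law report, hub list, signature, risk scores, train/test
#' evaluations, a genome-wide control-signature comparison, and optional
#' split-half stability and gene-set enrichment reports. A manifest
#' records the package version, all parameters and seeds, so a rerun from
#' the manifest reproduces every output byte for byte. Any stage failure
#' aborts with the stage named.
#'
#' @param m Methylation matrix.
#' @param clinical Clinical table.
#' @param output_dir Directory for artifacts (created if absent).
#' @param k,hub_fraction,alpha Pipeline parameters (defaults 10, 0.10,
#'   0.05, matching the construction the package implements).
#' @param split_seed Seed of the 50/50 train/test split (default 1).
#' @param stability_B Number of split-half stability replicates; 0 skips
#'   the stability stage (it refits Cox per feature per half per replicate
#'   and dominates the runtime on large matrices).
#' @param annotation Optional probe annotation (from [read_annotation()]).
#' @param gene_sets Optional gene-set collection (from [read_gmt()]);
#'   hub enrichment runs when both annotation and gene_sets are given.
#' @param chunk_size Passed to [build_rank_network()].
#' @return Invisibly, a list with the fitted objects and artifact paths.
#' @export
run_pipeline <- function(m, clinical, output_dir,
                         k = 10, hub_fraction = 0.10, alpha = 0.05,
                         split_seed = 1, stability_B = 0,
                         annotation = NULL, gene_sets = NULL,
                         chunk_size = 512L) {
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stopf("pipeline stage '%s' failed: %s", name, conditionMessage(e)))
  }
  out <- function(f) file.path(output_dir, f)
  tsv <- function(df, f) utils::write.table(df, out(f), sep = "\t",
                                            quote = FALSE, row.names = FALSE)

  al <- stage("align", align_samples(m, clinical))
  split <- stage("split", split_train_test(al$clinical$sample, split_seed))
  m_train <- al$m[, split$train, drop = FALSE]
  m_test <- al$m[, split$test, drop = FALSE]

  fit <- stage("fit", methnet_fit(m_train, al$clinical, k = k,
                                  hub_fraction = hub_fraction, alpha = alpha,
                                  chunk_size = chunk_size))
  stage("network_artifacts", {
    write_edge_list(fit$network, out("edge_list.tsv"))
    tsv(fit$degree_distribution, "degree_distribution.tsv")
    if (!is.null(fit$powerlaw))
      jsonlite::write_json(fit$powerlaw[c("exponent", "intercept", "correlation",
                                          "r_squared", "raw_correlation")],
                           out("powerlaw.json"), auto_unbox = TRUE, digits = NA)
    tsv(data.frame(site = fit$hubs$sites,
                   degree = fit$network$degree[fit$hubs$sites]), "hubs.tsv")
    tsv(fit$signature$entries, "signature.tsv")
  })

  eval_json <- function(ev) list(label = ev$label, n = ev$n,
                                 logrank_chi_square = ev$logrank$chi_square,
                                 logrank_p = ev$logrank$p_value,
                                 hr = ev$hr$hr, hr_ci_low = ev$hr$ci_low,
                                 hr_ci_high = ev$hr$ci_high)
  ev_train <- stage("evaluate_train",
                    evaluate_signature(fit$signature, m_train, al$clinical, "train"))
  ev_test <- stage("evaluate_test",
                   evaluate_signature(fit$signature, m_test, al$clinical, "test"))
  ctrl <- stage("control_signature",
                control_signature(m_train, al$clinical, nrow(fit$signature$entries)))
  ev_ctrl <- stage("evaluate_control",
                   evaluate_signature(ctrl, m_test, al$clinical, "control_test"))
  stage("evaluation_artifacts", {
    tsv(stratify(compute_risk_scores(fit$signature, al$m)), "risk_scores.tsv")
    jsonlite::write_json(list(train = eval_json(ev_train), test = eval_json(ev_test),
                              control_test = eval_json(ev_ctrl)),
                         out("evaluation.json"), auto_unbox = TRUE, digits = NA)
  })

  stability <- NULL
  if (stability_B > 0) {
    stability <- stage("stability",
                       run_stability(al$m, al$clinical, B = stability_B,
                                     alpha = alpha, seed = split_seed,
                                     platform = "methylation"))
    stage("stability_artifacts", tsv(stability$table, "stability.tsv"))
  }

  enrichment <- NULL
  if (!is.null(annotation) && !is.null(gene_sets)) {
    enrichment <- stage("enrichment", {
      universe <- sites_to_genes(rownames(al$m), annotation)
      query <- sites_to_genes(fit$hubs$sites, annotation)
      enrich(query, gene_sets, universe)
    })
    stage("enrichment_artifacts", tsv(enrichment, "enrichment.tsv"))
  }

  stage("manifest", jsonlite::write_json(
    list(package = "methnetprog",
         version = as.character(utils::packageVersion("methnetprog")),
         parameters = list(k = k, hub_fraction = hub_fraction, alpha = alpha,
                           split_seed = split_seed, stability_B = stability_B),
         data = list(n_sites = nrow(al$m), n_samples = ncol(al$m),
                     n_train = length(split$train), n_test = length(split$test)),
         seeds = list(split = split_seed,
                      stability = if (stability_B > 0) split_seed else NULL)),
    out("manifest.json"), auto_unbox = TRUE, digits = NA))

  invisible(list(fit = fit, split = split,
                 evaluations = list(train = ev_train, test = ev_test,
                                    control_test = ev_ctrl),
                 control = ctrl, stability = stability, enrichment = enrichment,
                 output_dir = output_dir))
}
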