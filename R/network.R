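#' Spearman rank correlation
#'
#' Rank correlation between two site vectors. With all ranks distinct this is
#' the classical 1 - 6 sum(d_i^2) / (n^3 - n), where d_i is the rank
#' difference in sample i; ties are handled by midranks (average ranks),
#' which makes the statistic the Pearson correlation of the rank vectors.
#'
#' @param x,y Numeric vectors of equal length (n >= 3), finite values.
#' @return The correlation rho in \[-1, 1\].
#' @examples
#' spearman_rho(c(0.1, 0.4, 0.8), c(0.2, 0.3, 0.9))  # identical orderings: 1
#' @export
spearman_rho <- function(x, y) {
  if (length(x) != length(y)) stopf("x and y must have equal length")
  n <- length(x)
  if (n < 3) stopf("need at least 3 samples, got %d", n)
  if (any(!is.finite(x)) || any(!is.finite(y))) stopf("non-finite values in input")
  rx <- rank(x)
  ry <- rank(y)
  rx <- rx - mean(rx)
  ry <- ry - mean(ry)
  sx2 <- sum(rx^2)
  sy2 <- sum(ry^2)
  if (sx2 == 0 || sy2 == 0)
    stopf("rank correlation undefined: %s vector is constant",
          if (sx2 == 0) "first" else "second")
  r <- sum(rx * ry) / sqrt(sx2 * sy2)
  max(-1, min(1, r))
}

# Row-wise rank transform, centered and scaled to unit sum of squares, so
# that Z %*% t(Z) is the matrix of pairwise Spearman correlations.
rank_standardize <- function(m) {
  z <- t(apply(m, 1L, rank))
  z <- z - rowMeans(z)
  ss <- sqrt(rowSums(z^2))
  if (any(ss == 0)) {
    bad <- rownames(m)[ss == 0]
    stopf("constant site(s) have undefined rank correlation: %s%s",
          paste(utils::head(bad, 5), collapse = ", "),
          if (length(bad) > 5) sprintf(" (+%d more)", length(bad) - 5) else "")
  }
  z / ss
}

#' Build a rank-based co-methylation interaction network
#'
#' For every CpG site the Spearman correlation against all other sites is
#' computed and the k partners with the largest absolute correlation are
#' kept as its neighbors ("most relevant" sites). The union of all selected
#' pairs is the interaction network. This per-node top-k rule adapts to
#' heterogeneous correlation scales: strongly co-methylated modules and
#' weakly coupled ones each contribute k neighbors per site, unlike a global
#' correlation threshold.
#'
#' Selection pairs are kept directed and unmerged (k per selector node), and
#' the deduplicated undirected edge view is derived from them; node degrees
#' count distinct neighbors in the undirected view. The correlation matrix is
#' processed in row blocks so the full N x N matrix is never materialized.
#'
#' @param m Methylation matrix, sites in rows (>= k+1), samples in columns
#'   (>= 3).
#' @param k Neighbors selected per site (default 10).
#' @param chunk_size Number of sites correlated per block (memory/speed
#'   trade-off only; the result is identical for any value).
#' @return An object of class \code{methnet}: a list with
#'   \describe{
#'     \item{selection_pairs}{data.frame (selector, selected, rho), exactly
#'       k rows per site, signed rho.}
#'     \item{edges}{deduplicated undirected edges (site_a < site_b) with rho
#'       and selected_by in \{a, b, both\}.}
#'     \item{degree}{named integer vector, distinct-neighbor degree per site.}
#'     \item{k, n_sites, n_samples}{parameters of the construction.}
#'   }
#' @export
build_rank_network <- function(m, k = 10, chunk_size = 512L) {
  assert_methylation_matrix(m)
  n_sites <- nrow(m)
  n_samp <- ncol(m)
  if (n_samp < 3) stopf("need at least 3 samples, got %d", n_samp)
  if (k < 1) stopf("k must be >= 1")
  if (k >= n_sites) stopf("k = %d must be smaller than the number of sites (%d)", k, n_sites)

  sites <- rownames(m)
  z <- rank_standardize(m)
  # Tie-break rank for "largest |rho| first, then site id": precompute the
  # lexicographic order of site ids once.
  id_rank <- rank(sites, ties.method = "first")

  sel_idx <- matrix(0L, nrow = n_sites, ncol = k)
  sel_rho <- matrix(NA_real_, nrow = n_sites, ncol = k)
  starts <- seq(1L, n_sites, by = as.integer(chunk_size))
  for (s in starts) {
    e <- min(s + chunk_size - 1L, n_sites)
    rho_blk <- z[s:e, , drop = FALSE] %*% t(z)  # rows: sites s..e vs all
    for (i in seq_len(e - s + 1L)) {
      row <- rho_blk[i, ]
      a <- abs(row)
      a[a > 1] <- 1  # numeric guard
      a[s + i - 1L] <- -Inf  # never self
      kth <- -sort.int(-a, partial = k)[k]
      cand <- which(a >= kth)
      if (length(cand) > k)
        cand <- cand[order(-a[cand], id_rank[cand])]
      top <- cand[seq_len(k)]
      sel_idx[s + i - 1L, ] <- top
      sel_rho[s + i - 1L, ] <- row[top]
    }
  }

  selector <- rep(seq_len(n_sites), each = k)
  selected <- as.integer(t(sel_idx))
  rho <- as.numeric(t(sel_rho))
  selection_pairs <- data.frame(selector = sites[selector],
                                selected = sites[selected],
                                rho = rho,
                                stringsAsFactors = FALSE)

  # Undirected dedup: canonical orientation is site_a < site_b by id.
  swap <- id_rank[selector] > id_rank[selected]
  site_a <- ifelse(swap, selection_pairs$selected, selection_pairs$selector)
  site_b <- ifelse(swap, selection_pairs$selector, selection_pairs$selected)
  key <- paste(site_a, site_b, sep = "\r")
  first <- !duplicated(key)
  dup_key <- key[duplicated(key)]
  selected_by <- ifelse(swap[first], "b", "a")
  selected_by[key[first] %in% dup_key] <- "both"
  edges <- data.frame(site_a = site_a[first],
                      site_b = site_b[first],
                      rho = rho[first],
                      selected_by = selected_by,
                      stringsAsFactors = FALSE)
  edges <- edges[order(edges$site_a, edges$site_b), , drop = FALSE]
  rownames(edges) <- NULL

  deg <- table(factor(c(edges$site_a, edges$site_b), levels = sites))
  degree <- structure(as.integer(deg), names = sites)

  structure(list(selection_pairs = selection_pairs,
                 edges = edges,
                 degree = degree,
                 k = as.integer(k),
                 n_sites = n_sites,
                 n_samples = n_samp),
            class = "methnet")
}

#' @export
print.methnet <- function(x, ...) {
  cat(sprintf("Rank-based co-methylation network (k = %d)\n", x$k))
  cat(sprintf("  %d sites, %d samples\n", x$n_sites, x$n_samples))
  cat(sprintf("  %d selection pairs, %d unique undirected edges\n",
              nrow(x$selection_pairs), nrow(x$edges)))
  cat(sprintf("  degree range %d-%d (median %g)\n",
              min(x$degree), max(x$degree), stats::median(x$degree)))
  invisible(x)
}

#' Degree distribution of a network
#'
#' Counts nodes by distinct-neighbor degree in the undirected edge view.
#'
#' @param net A \code{methnet} object.
#' @return data.frame (degree, count); counts sum to the node count.
#' @export
degree_distribution <- function(net) {
  if (!inherits(net, "methnet")) stopf("`net` must be a methnet object")
  tab <- table(net$degree)
  data.frame(degree = as.integer(names(tab)),
             count = as.integer(tab))
}

#' Fit a power law to a degree distribution
#'
#' Ordinary least squares of log10(count) on log10(degree): the straight-line
#' diagnostic for scale-free topology. The slope is the power-law exponent.
#' The Pearson correlation of the untransformed (degree, count) points is
#' also reported (some network-analysis tools print that convention); the
#' log-log fit is the primary one.
#'
#' @param dist data.frame (degree, count) as from [degree_distribution()],
#'   needing >= 3 distinct degrees with positive counts.
#' @return Object of class \code{powerlaw_fit} with exponent (slope),
#'   intercept, correlation (Pearson r of the log-log points), r_squared,
#'   and raw_correlation (Pearson r of the untransformed points).
#' @export
fit_power_law <- function(dist) {
  if (!is.data.frame(dist) || !all(c("degree", "count") %in% names(dist)))
    stopf("`dist` must be a data.frame with columns degree, count")
  dist <- dist[dist$count > 0 & dist$degree > 0, , drop = FALSE]
  if (length(unique(dist$degree)) < 3)
    stopf("need at least 3 distinct degrees with positive counts, got %d",
          length(unique(dist$degree)))
  lx <- log10(dist$degree)
  ly <- log10(dist$count)
  fit <- stats::lm(ly ~ lx)
  # constant counts have no defined correlation (degenerate flat fit)
  r <- if (stats::sd(ly) == 0) NA_real_ else stats::cor(lx, ly)
  raw <- if (stats::sd(dist$count) == 0) NA_real_ else
    stats::cor(dist$degree, dist$count)
  structure(list(exponent = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 correlation = r,
                 r_squared = r^2,
                 raw_correlation = raw,
                 n_points = nrow(dist)),
            class = "powerlaw_fit")
}

#' @export
print.powerlaw_fit <- function(x, ...) {
  cat("Power-law fit of the degree distribution (log10-log10 OLS)\n")
  cat(sprintf("  count ~ degree^%.3f   (intercept %.3f, %d points)\n",
              x$exponent, x$intercept, x$n_points))
  cat(sprintf("  correlation %.3f, R-squared %.3f\n", x$correlation, x$r_squared))
  invisible(x)
}

#' Select hub sites by degree
#'
#' Hubs are the top fraction of nodes by degree. The degree threshold is the
#' largest degree d such that at least ceiling(fraction * N) nodes have
#' degree >= d; all nodes at or above the threshold are included, so degree
#' ties at the cut can make the hub set slightly larger than fraction * N.
#'
#' @param net A \code{methnet} object.
#' @param fraction Target fraction of nodes (default 0.10).
#' @return Object of class \code{hub_set}: list with sites (character),
#'   degree_threshold, fraction, n_nodes.
#' @export
select_hubs <- function(net, fraction = 0.10) {
  if (!inherits(net, "methnet")) stopf("`net` must be a methnet object")
  if (!(fraction > 0 && fraction < 1)) stopf("fraction must be in (0, 1)")
  deg <- net$degree
  target <- ceiling(fraction * length(deg))
  dd <- sort(unique(deg), decreasing = TRUE)
  cum <- cumsum(as.integer(table(factor(deg, levels = dd))))
  threshold <- dd[which(cum >= target)[1]]
  sites <- names(deg)[deg >= threshold]
  structure(list(sites = sort(sites),
                 degree_threshold = as.integer(threshold),
                 fraction = fraction,
                 n_nodes = length(deg)),
            class = "hub_set")
}

#' @export
print.hub_set <- function(x, ...) {
  cat(sprintf("Hub set: %d of %d sites (target fraction %.2g), degree >= %d\n",
              length(x$sites), x$n_nodes, x$fraction, x$degree_threshold))
  invisible(x)
}
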