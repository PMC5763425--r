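#' Map CpG sites to gene symbols
#'
#' Union of the genes annotated to the given sites, deduplicated. Probes
#' annotated to several genes (overlapping transcripts) contribute each
#' gene once. Unmapped sites are counted and reported as a message.
#'
#' @param sites Character vector of site ids.
#' @param annotation Named list from [read_annotation()] (site -> genes).
#' @return Sorted character vector of unique gene symbols.
#' @export
sites_to_genes <- function(sites, annotation) {
  mapped <- sites[sites %in% names(annotation)]
  n_unmapped <- length(sites) - length(mapped)
  if (n_unmapped > 0)
    warnf("%d of %d sites have no gene annotation", n_unmapped, length(sites))
  sort(unique(unlist(annotation[mapped], use.names = FALSE)))
}

#' Gene-set over-representation by the hypergeometric test
#'
#' For each gene set, tests whether its overlap with the query is larger
#' than expected when drawing \code{|query|} genes from the universe:
#' [hypergeometric_overlap_p()] with x = overlap, K = query size,
#' N = set size within the universe, M = universe size. P-values are
#' adjusted across sets with Benjamini-Hochberg.
#'
#' @param query Character vector of query genes (e.g. hub genes); genes
#'   outside the universe are dropped with a warning.
#' @param sets Named list of gene sets, as from [read_gmt()]; each set is
#'   intersected with the universe before testing.
#' @param universe Character vector of all genes the query was drawn from.
#' @return data.frame (set, overlap, set_size, query_size, universe_size,
#'   p_value, fdr_q) sorted by p_value.
#' @export
enrich <- function(query, sets, universe) {
  universe <- unique(universe)
  if (length(universe) == 0) stopf("empty gene universe")
  query <- unique(query)
  outside <- setdiff(query, universe)
  if (length(outside) > 0) {
    warnf("%d query gene(s) outside the universe were dropped", length(outside))
    query <- intersect(query, universe)
  }
  M <- length(universe)
  K <- length(query)
  res <- lapply(names(sets), function(nm) {
    members <- intersect(sets[[nm]], universe)
    x <- length(intersect(query, members))
    data.frame(set = nm, overlap = x, set_size = length(members),
               query_size = K, universe_size = M,
               p_value = if (length(members) == 0) 1
                         else hypergeometric_overlap_p(x, K, length(members), M),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$fdr_q <- stats::p.adjust(out$p_value, method = "BH")
  out <- out[order(out$p_value, out$set), , drop = FALSE]
  rownames(out) <- NULL
  out
}
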