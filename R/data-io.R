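#' Read a methylation beta-value matrix
#'
#' Reads a tab-separated matrix of DNA methylation beta values with CpG site
#' ids in the first column and one header column per sample. Beta values are
#' fractions in \[0, 1\] (methylated over total signal). Sites containing any
#' missing value are dropped (rank correlations require complete site
#' vectors); the number dropped is reported as a warning.
#'
#' @param path Path to a TSV file. The first column holds site ids, the
#'   header row holds sample ids. Ids are case-sensitive.
#' @return A numeric matrix, sites in rows (rownames = site ids), samples in
#'   columns (colnames = sample ids), all values in \[0, 1\].
#' @examples
#' tf <- tempfile(fileext = ".tsv")
#' writeLines(c("site\ts1\ts2", "cg01\t0.1\t0.9", "cg02\t0.5\t0.4"), tf)
#' m <- read_methylation_matrix(tf)
#' dim(m)
#' @export
read_methylation_matrix <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2) stopf("matrix file '%s' needs a site-id column plus >=1 sample column", path)
  sites <- as.character(df[[1]])
  samples <- colnames(df)[-1]
  if (anyDuplicated(sites)) stopf("duplicate site ids in '%s': %s", path,
                                  paste(unique(sites[duplicated(sites)]), collapse = ", "))
  if (anyDuplicated(samples)) stopf("duplicate sample ids in '%s': %s", path,
                                    paste(unique(samples[duplicated(samples)]), collapse = ", "))
  m <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(m)) stopf("non-numeric beta values in '%s'", path)
  rownames(m) <- sites
  bad <- which(!is.na(m) & (m < 0 | m > 1), arr.ind = TRUE)
  if (nrow(bad) > 0) {
    stopf("beta value %.4g outside [0, 1] at site '%s', sample '%s' in '%s'",
          m[bad[1, 1], bad[1, 2]], sites[bad[1, 1]], samples[bad[1, 2]], path)
  }
  has_na <- rowSums(is.na(m)) > 0
  if (any(has_na)) {
    warnf("dropped %d of %d sites with missing beta values", sum(has_na), nrow(m))
    m <- m[!has_na, , drop = FALSE]
  }
  m
}

#' Read a clinical survival table
#'
#' Reads a TSV with columns \code{sample}, \code{time_days} (positive
#' follow-up time in days) and \code{event} (1 = death observed,
#' 0 = censored).
#'
#' @param path Path to the TSV file.
#' @return A data.frame with columns sample (character), time_days (numeric),
#'   event (integer 0/1).
#' @export
read_clinical <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("sample", "time_days", "event")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0) stopf("clinical file '%s' missing columns: %s", path, paste(miss, collapse = ", "))
  cl <- data.frame(sample = as.character(df$sample),
                   time_days = as.numeric(df$time_days),
                   event = as.integer(df$event),
                   stringsAsFactors = FALSE)
  assert_clinical(cl)
  cl
}

#' Restrict a matrix and clinical table to their shared samples
#'
#' Both inputs are restricted to the intersection of their sample ids, in
#' identical order (the order of first appearance in the matrix). Only
#' samples with both methylation and clinical data are analysed.
#'
#' @param m Methylation matrix (sites x samples).
#' @param clinical Clinical table as from [read_clinical()].
#' @return A list with elements \code{m} and \code{clinical}, sample-aligned.
#' @export
align_samples <- function(m, clinical) {
  assert_methylation_matrix(m)
  assert_clinical(clinical)
  shared <- intersect(colnames(m), clinical$sample)
  if (length(shared) == 0) stopf("no samples shared between matrix and clinical table")
  list(m = m[, shared, drop = FALSE],
       clinical = clinical[match(shared, clinical$sample), , drop = FALSE])
}

#' Read a GMT gene-set collection
#'
#' Standard GMT semantics: one set per line, tab-separated as
#' name, description, member genes.
#'
#' @param path Path to the GMT file.
#' @return A named list of character vectors of gene symbols; the
#'   \code{"description"} attribute on each element carries the GMT
#'   description field.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sets <- vector("list", length(lines))
  nms <- character(length(lines))
  for (i in seq_along(lines)) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < 3) stopf("malformed GMT line %d in '%s' (need name, description, >=1 gene)", i, path)
    genes <- unique(f[-(1:2)])
    genes <- genes[nzchar(genes)]
    if (length(genes) == 0) stopf("empty gene set at GMT line %d in '%s'", i, path)
    nms[i] <- f[1]
    sets[[i]] <- structure(genes, description = f[2])
  }
  if (anyDuplicated(nms)) stopf("duplicate set names in '%s'", path)
  names(sets) <- nms
  sets
}

#' Read a probe-to-gene annotation table
#'
#' TSV with two columns: site id, then a comma-separated list of gene
#' symbols. Array probes frequently map to more than one gene (overlapping
#' transcripts); all listed genes are kept.
#'
#' @param path Path to the TSV file (no header).
#' @return A named list: site id -> character vector of gene symbols.
#' @export
read_annotation <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  ann <- vector("list", length(lines))
  ids <- character(length(lines))
  for (i in seq_along(lines)) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) != 2) stopf("malformed annotation line %d in '%s' (need site<TAB>genes)", i, path)
    genes <- trimws(strsplit(f[2], ",", fixed = TRUE)[[1]])
    genes <- genes[nzchar(genes)]
    if (length(genes) == 0) stopf("no genes for site '%s' at line %d in '%s'", f[1], i, path)
    ids[i] <- f[1]
    ann[[i]] <- genes
  }
  if (anyDuplicated(ids)) stopf("duplicate site ids in annotation '%s'", path)
  names(ann) <- ids
  ann
}

#' Write / read a network edge list
#'
#' The deduplicated undirected edge view of a co-methylation network is
#' serialized as a TSV with columns site_a, site_b, rho and selected_by
#' (which endpoint's top-k selection produced the edge: "a", "b" or "both").
#'
#' @param net A network from [build_rank_network()], or a data.frame with
#'   the four edge columns.
#' @param path Output path.
#' @return \code{write_edge_list} returns \code{path} invisibly;
#'   \code{read_edge_list} returns the edge data.frame.
#' @export
write_edge_list <- function(net, path) {
  edges <- if (is.data.frame(net)) net else net$edges
  need <- c("site_a", "site_b", "rho", "selected_by")
  if (!all(need %in% names(edges))) stopf("edge table must have columns %s", paste(need, collapse = ", "))
  utils::write.table(edges[, need], path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_edge_list
#' @export
read_edge_list <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("site_a", "site_b", "rho", "selected_by")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0) stopf("edge list '%s' missing columns: %s", path, paste(miss, collapse = ", "))
  if (!all(df$selected_by %in% c("a", "b", "both")))
    stopf("edge list '%s': selected_by must be one of a, b, both", path)
  df
}
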