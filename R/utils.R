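# Internal helpers shared across modules.

# Evaluate `code` under a fixed RNG state, restoring the caller's stream.
# Mersenne-Twister + inversion are pinned so results do not depend on the
# session's RNGkind.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed), kind = "Mersenne-Twister", normal.kind = "Inversion")
  force(code)
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

assert_methylation_matrix <- function(m, arg = "m") {
  if (!is.matrix(m) || !is.numeric(m))
    stopf("`%s` must be a numeric matrix (sites in rows, samples in columns)", arg)
  if (is.null(rownames(m)) || is.null(colnames(m)))
    stopf("`%s` must have site ids as rownames and sample ids as colnames", arg)
  if (anyDuplicated(rownames(m))) stopf("duplicate site ids in `%s`", arg)
  if (anyDuplicated(colnames(m))) stopf("duplicate sample ids in `%s`", arg)
  invisible(m)
}

assert_clinical <- function(cl, arg = "clinical") {
  need <- c("sample", "time_days", "event")
  if (!is.data.frame(cl) || !all(need %in% names(cl)))
    stopf("`%s` must be a data.frame with columns sample, time_days, event", arg)
  if (anyDuplicated(cl$sample)) stopf("duplicate sample ids in `%s`", arg)
  if (any(!is.finite(cl$time_days)) || any(cl$time_days <= 0))
    stopf("`%s`: time_days must be positive and finite", arg)
  if (!all(cl$event %in% c(0, 1)))
    stopf("`%s`: event must be 0 (censored) or 1 (death observed)", arg)
  invisible(cl)
}
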