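# Shared fixtures and independent oracles for the test suite.

# small complete-data toy used for the enumeration / Monte-Carlo checks
toy_data <- function() {
  matrix(c(0.9, 0.8,
           0.85, 0.9,
           0.05, 0.1), nrow = 3, byrow = TRUE)
}

# exhaustive posterior over binary feature matrices with at most kmax
# columns: enumerates every multiset of nonzero column patterns, weighs it
# by the buffet-process class prior times the collapsed likelihood, and
# normalises. Returns a named vector of class probabilities keyed by the
# sorted column patterns ("" for the empty matrix).
enumerate_toy_posterior <- function(X, alpha, sigma_x, sigma_a, kmax = 2L) {
  n <- nrow(X)
  h_n <- sum(1 / seq_len(n))
  cols <- lapply(seq_len(2^n - 1), function(b) as.integer(intToBits(b)[1:n]))
  col_key <- vapply(cols, paste0, "", collapse = "")
  log_col_prior <- vapply(cols, function(z) {
    m <- sum(z)
    lfactorial(n - m) + lfactorial(m - 1) - lfactorial(n)
  }, 0)

  keys <- character(0); logw <- numeric(0)
  add <- function(idx) {
    k <- length(idx)
    Z <- if (k == 0) matrix(0, n, 0) else do.call(cbind, cols[idx])
    mult <- table(idx)
    lp <- k * log(alpha) - alpha * h_n - sum(lfactorial(mult)) +
      sum(log_col_prior[idx]) +
      collapsed_log_likelihood(Z, X, sigma_x, sigma_a)
    keys <<- c(keys, paste(sort(col_key[idx]), collapse = "|"))
    logw <<- c(logw, lp)
  }
  add(integer(0))
  for (i in seq_along(cols)) {
    if (kmax >= 1) add(i)
    if (kmax >= 2) for (j in i:length(cols)) add(c(i, j))
  }
  w <- exp(logw - max(logw))
  stats::setNames(w / sum(w), keys)
}

# canonical multiset key of a sampled state, for tallying against the oracle
state_key <- function(Z) {
  if (ncol(Z) == 0) return("")
  paste(sort(apply(Z, 2, paste0, collapse = "")), collapse = "|")
}

# three-row EMA table on the default schema, written to a temp file
write_tiny_ema <- function(path = tempfile(fileext = ".csv")) {
  writeLines(c(
    "patient_id,timestamp,question_id,raw_value",
    "P001,2019-11-02T10:30:00,wish_die,7",
    "P001,2019-11-02T14:05:00,sleep_02,4",
    "P002,2020-03-20T11:00:00,wish_live,2.5"
  ), path)
  path
}

# memoised study-scale pipeline run shared by the acceptance tests
.acceptance_cache <- new.env(parent = emptyenv())
study_scale_run <- function(seed = 20211L) {
  key <- paste0("run_", seed)
  if (is.null(.acceptance_cache[[key]])) {
    out <- file.path(tempdir(), paste0("emaprofiles-accept-", seed))
    .acceptance_cache[[key]] <- run_pipeline(out, seed = seed)
  }
  .acceptance_cache[[key]]
}
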