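#' Assign each observation to a risk profile
#'
#' A profile is a distinct feature-activation pattern: two observations
#' belong to the same profile exactly when they own the same set of latent
#' features. With `K` features at most `2^K` profiles exist, and the
#' all-zero pattern — no risk feature active — is a valid profile. Profiles
#' are numbered `1..P` by descending overall prevalence, ties broken by the
#' pattern read as a binary integer, ascending.
#'
#' With `method = "map_pattern"` (the default whenever the observation
#' matrix is supplied) each row's pattern is the mode of its conditional
#' posterior given the fitted state: the pattern maximising the product of
#' the process prior (`m_k / N` per feature) and the Gaussian likelihood
#' over the row's observed entries. This de-noises labels for rows whose few
#' observed items carry no information about a feature — a single sampled
#' `Z` row would activate such features with probability `m_k / N`, which
#' distorts prevalence under heavy turn-over missingness. `"sampled_pattern"`
#' uses the rows of `Z` as drawn. `"dominant"` labels each row by its
#' most-owned active feature, with all-zero rows as a baseline class.
#'
#' @param map_state An `ibp_state`, normally the `map_state` of a fitted
#'   [run_gibbs()] posterior.
#' @param obs The `observation_matrix` the state was fitted to (row order
#'   must match); required for `"map_pattern"`.
#' @param method `"map_pattern"`, `"sampled_pattern"` or `"dominant"`.
#'   Default: `"map_pattern"` when `obs` is supplied, else
#'   `"sampled_pattern"`.
#' @return An object of class `profile_assignment`: list with `labels`
#'   (integer per row), `patterns` (P x K binary matrix, one row per
#'   profile), `prevalence` (named numeric summing to 1) and `n_rows`.
#' @export
assign_profiles <- function(map_state, obs = NULL,
                            method = c("auto", "map_pattern",
                                       "sampled_pattern", "dominant")) {
  method <- match.arg(method)
  if (method == "auto") {
    method <- if (is.null(obs)) "sampled_pattern" else "map_pattern"
  }
  stopifnot(inherits(map_state, "ibp_state"))
  Z <- map_state$Z
  n <- nrow(Z)
  if (n == 0L) stop("empty state: no rows to assign")
  if (method == "map_pattern") {
    key <- .map_pattern_keys(map_state, obs)
  } else if (method == "sampled_pattern") {
    key <- if (ncol(Z) > 0) apply(Z, 1, paste0, collapse = "") else rep("", n)
  } else {
    ord <- feature_order(Z)  # most-owned feature first
    key <- apply(Z, 1, function(z) {
      act <- ord[which(z[ord] == 1)]
      if (length(act) == 0) "baseline" else paste0("f", act[1])
    })
  }
  method_label <- if (method == "dominant") "dominant" else "pattern"
  counts <- table(key)
  pat_keys <- names(counts)
  # binary-integer value of each pattern for the tie break
  pat_int <- if (method_label == "pattern") {
    vapply(pat_keys, function(k) strtoi(k, base = 2L), 0)
  } else {
    seq_along(pat_keys)
  }
  pat_int[is.na(pat_int)] <- 0
  ord <- order(-as.integer(counts), pat_int)
  pat_keys <- pat_keys[ord]
  labels <- match(key, pat_keys)
  prevalence <- as.numeric(counts[ord]) / n
  names(prevalence) <- paste0("profile_", seq_along(pat_keys))
  patterns <- if (method_label == "pattern" && ncol(Z) > 0) {
    t(vapply(pat_keys,
             function(k) as.integer(strsplit(k, "")[[1]]),
             integer(ncol(Z))))
  } else {
    matrix(NA_integer_, length(pat_keys), max(1L, ncol(Z)),
           dimnames = list(pat_keys, NULL))
  }
  structure(list(labels = labels, patterns = patterns,
                 prevalence = prevalence, n_rows = n, method = method),
            class = "profile_assignment")
}

# accept an observation_matrix, a list with values/mask, or a bare matrix
.obs_values_mask <- function(obs) {
  if (is.list(obs) && !is.null(obs$values)) {
    values <- as.matrix(obs$values)
    mask <- if (!is.null(obs$mask)) obs$mask else !is.na(values)
  } else {
    values <- as.matrix(obs)
    mask <- !is.na(values)
  }
  list(values = values, mask = mask)
}

# per-row posterior-mode feature pattern given the fitted state
.map_pattern_keys <- function(state, obs) {
  if (is.null(obs)) stop("method 'map_pattern' needs the observation matrix")
  ov <- .obs_values_mask(obs)
  values <- ov$values; mask <- ov$mask
  Z <- state$Z
  n <- nrow(Z); k <- ncol(Z)
  if (nrow(values) != n) {
    stop("observation matrix rows do not match the fitted state")
  }
  if (k == 0L) return(rep("", n))
  if (k > 12L) stop("map_pattern assignment supports at most 12 features")
  pats <- as.matrix(expand.grid(rep(list(0:1), k)))[, k:1, drop = FALSE]
  # clamp away from {0, 1} so a universally-owned feature cannot produce
  # 0 * -Inf in the prior product
  p_k <- pmin(pmax(colSums(Z) / n, 1 / (2 * n)), 1 - 1 / (2 * n))
  log_prior <- pats %*% log(p_k) + (1 - pats) %*% log1p(-p_k)
  ll <- matrix(0, n, nrow(pats))
  for (j in seq_len(nrow(pats))) {
    pred <- as.numeric(pats[j, ] %*% state$A)
    if (!is.null(state$mu)) pred <- pred + state$mu
    dm <- stats::dnorm(values, matrix(pred, n, length(pred), byrow = TRUE),
                       state$sigma_x, log = TRUE)
    dm[!mask] <- 0
    ll[, j] <- rowSums(dm) + log_prior[j]
  }
  best <- max.col(ll, ties.method = "first")
  apply(pats, 1, paste0, collapse = "")[best]
}

#' @export
print.profile_assignment <- function(x, ...) {
  cat("profile_assignment:", length(x$prevalence), "profiles over",
      x$n_rows, "observations\n")
  print(round(x$prevalence, 4))
  invisible(x)
}

#' Per-profile variable signatures
#'
#' The signature of a profile is, for each of the 32 items, the probability
#' of scoring positive: the fraction of that profile's observations with an
#' observed, positive (binarized) score on the item. Cells with no observed
#' entries are `NA` — unknown, not zero.
#'
#' @param assignment A [assign_profiles()] result.
#' @param obs An `observation_matrix` (row order must match the fitted data).
#' @param threshold Binarization threshold passed to [binarize()];
#'   default 0.5.
#' @return P x D numeric matrix of positive-score probabilities (rows:
#'   profiles in prevalence order; columns: schema items), with `NA` where a
#'   profile has no observation of an item.
#' @export
feature_signature <- function(assignment, obs, threshold = 0.5) {
  stopifnot(inherits(assignment, "profile_assignment"))
  ov <- .obs_values_mask(obs)
  values <- ov$values; mask <- ov$mask
  if (nrow(values) != length(assignment$labels)) {
    stop("observation matrix has ", nrow(values), " rows but assignment has ",
         length(assignment$labels), " labels")
  }
  pos <- binarize(values, threshold) & mask
  p <- length(assignment$prevalence)
  sig <- matrix(NA_real_, p, ncol(values),
                dimnames = list(names(assignment$prevalence), colnames(values)))
  for (pp in seq_len(p)) {
    rows <- assignment$labels == pp
    if (!any(rows)) {
      warning("profile ", pp, " has no rows; excluded from signatures")
      next
    }
    n_obs <- colSums(mask[rows, , drop = FALSE])
    n_pos <- colSums(pos[rows, , drop = FALSE])
    sig[pp, ] <- ifelse(n_obs > 0, n_pos / n_obs, NA_real_)
  }
  sig
}

#' Cumulative prevalence of the top profiles
#'
#' @param assignment A [assign_profiles()] result.
#' @param top_m Number of leading profiles to sum (1..P).
#' @return Fraction of observations covered by profiles `1..top_m`.
#' @export
coverage <- function(assignment, top_m) {
  stopifnot(inherits(assignment, "profile_assignment"))
  p <- length(assignment$prevalence)
  if (top_m < 1 || top_m > p) {
    stop("top_m must be in 1..", p, ", got ", top_m)
  }
  sum(assignment$prevalence[seq_len(top_m)])
}

#' Write profile-analysis artifacts to a directory
#'
#' Writes `assignment.csv` (`row_id,profile`), `prevalence.csv` and
#' `signatures.csv` (profiles x items).
#'
#' @param assignment A [assign_profiles()] result.
#' @param signatures Matrix from [feature_signature()], or `NULL` to skip.
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_profile_artifacts <- function(assignment, signatures = NULL, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(data.frame(row_id = seq_along(assignment$labels),
                              profile = assignment$labels),
                   file.path(dir, "assignment.csv"), row.names = FALSE)
  utils::write.csv(data.frame(profile = names(assignment$prevalence),
                              prevalence = as.numeric(assignment$prevalence)),
                   file.path(dir, "prevalence.csv"), row.names = FALSE)
  if (!is.null(signatures)) {
    utils::write.csv(as.data.frame(signatures),
                     file.path(dir, "signatures.csv"), row.names = TRUE)
  }
  invisible(dir)
}
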