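#' Sampler configuration for the latent-feature model
#'
#' @param n_iterations Total Gibbs sweeps; default 2000.
#' @param burn_in Sweeps discarded before retention; default 1000.
#' @param thin Keep every `thin`-th post-burn-in state; default 5.
#' @param seed Integer RNG seed; the whole run is deterministic given it.
#' @param resample_alpha Resample the IBP concentration from its conjugate
#'   Gamma posterior each sweep; default `TRUE`.
#' @param alpha_prior `c(shape, rate)` of the Gamma prior on the
#'   concentration; default `c(1, 1)`.
#' @param max_new_features_per_step Cap on the Poisson new-feature proposal
#'   per row update; default 4.
#' @param max_features Hard cap on the total number of active features
#'   (proposals that would exceed it are rejected); default `Inf`. Mainly
#'   used to compare against exhaustive enumeration on toy problems.
#' @param k_init Number of random features the chain starts from (ownership
#'   Bernoulli(1/2); redundant features are pruned during burn-in); default
#'   5. Starting from an empty matrix makes feature discovery depend
#'   entirely on singleton proposals, which mix slowly on large sparse data.
#' @return An object of class `gibbs_config`.
#' @export
gibbs_config <- function(n_iterations = 2000L, burn_in = 1000L, thin = 5L,
                         seed = 1L, resample_alpha = TRUE,
                         alpha_prior = c(1, 1),
                         max_new_features_per_step = 4L, max_features = Inf,
                         k_init = 5L) {
  stopifnot(burn_in < n_iterations, thin >= 1L, max_new_features_per_step >= 1L,
            length(alpha_prior) == 2L, all(alpha_prior > 0), k_init >= 0L)
  structure(list(n_iterations = as.integer(n_iterations),
                 burn_in = as.integer(burn_in), thin = as.integer(thin),
                 seed = as.integer(seed), resample_alpha = resample_alpha,
                 alpha_prior = alpha_prior,
                 max_new_features_per_step = as.integer(max_new_features_per_step),
                 max_features = max_features, k_init = as.integer(k_init)),
            class = "gibbs_config")
}

#' Create a latent-feature model state
#'
#' @param Z N x K binary feature-ownership matrix.
#' @param A K x D real weight matrix.
#' @param alpha IBP concentration (> 0).
#' @param sigma_x Observation noise sd (> 0).
#' @param sigma_a Weight prior sd (> 0).
#' @return An object of class `ibp_state`.
#' @export
ibp_state <- function(Z, A, alpha = 1, sigma_x = 0.25, sigma_a = 0.5) {
  Z <- as.matrix(Z); storage.mode(Z) <- "double"
  A <- as.matrix(A)
  stopifnot(all(Z %in% c(0, 1)), ncol(Z) == nrow(A),
            alpha > 0, sigma_x > 0, sigma_a > 0)
  if (ncol(Z) > 0 && any(colSums(Z) == 0)) {
    stop("state contains an all-zero feature column")
  }
  structure(list(Z = Z, A = A, alpha = alpha, sigma_x = sigma_x,
                 sigma_a = sigma_a, K = ncol(Z)),
            class = "ibp_state")
}

#' Prior inclusion probability of an existing feature
#'
#' Under the Indian buffet process, row `i` owns an already-expressed feature
#' `k` with prior probability `m / N`, where `m` is the number of other rows
#' owning the feature and `N` the total number of rows.
#'
#' @param k Feature (column) index.
#' @param i Row index.
#' @param Z Binary ownership matrix.
#' @return The probability `m / N`.
#' @export
ibp_prior_existing_prob <- function(k, i, Z) {
  m <- sum(Z[-i, k])
  if (m == 0) {
    stop("feature ", k, " is a singleton of row ", i,
         ": retired columns are handled by the new-feature step, ",
         "not this conditional")
  }
  m / nrow(Z)
}

# log IBP probability of the equivalence class of Z (left-ordered form)
.ibp_log_prior <- function(Z, alpha) {
  n <- nrow(Z); k <- ncol(Z)
  h_n <- sum(1 / seq_len(n))
  if (k == 0L) return(-alpha * h_n)
  m <- colSums(Z)
  key <- apply(Z, 2, paste0, collapse = "")
  mult <- table(key)
  k * log(alpha) - alpha * h_n - sum(lfactorial(mult)) +
    sum(lfactorial(n - m) + lfactorial(m - 1) - lfactorial(n))
}

# masked Gaussian log-likelihood of all observed cells
.masked_loglik <- function(Z, A, values, mask, sigma_x, mu = NULL) {
  if (ncol(Z) == 0L) {
    pred <- matrix(0, nrow(values), ncol(values))
  } else {
    pred <- Z %*% A
  }
  if (!is.null(mu)) pred <- sweep(pred, 2, mu, "+")
  sum(stats::dnorm(values[mask], pred[mask], sigma_x, log = TRUE))
}

# joint log-probability used for the trace and MAP selection
.joint_logp <- function(state, values, mask, sigma_mu = 0.5) {
  lp <- .ibp_log_prior(state$Z, state$alpha) +
    .masked_loglik(state$Z, state$A, values, mask, state$sigma_x, state$mu)
  if (state$K > 0) {
    lp <- lp + sum(stats::dnorm(state$A, 0, state$sigma_a, log = TRUE))
  }
  if (!is.null(state$mu)) {
    lp <- lp + sum(stats::dnorm(state$mu, 0, sigma_mu, log = TRUE))
  }
  lp
}

# conjugate draw of the per-item intercept given Z, A and the observed cells
.sample_intercept <- function(state, values, mask, sigma_mu = 0.5) {
  resid <- values
  if (state$K > 0) resid <- values - state$Z %*% state$A
  sx2 <- state$sigma_x^2
  mu <- numeric(ncol(values))
  for (d in seq_len(ncol(values))) {
    rows <- mask[, d]
    n_d <- sum(rows)
    prec <- n_d / sx2 + 1 / sigma_mu^2
    mean_d <- sum(resid[rows, d]) / sx2 / prec
    mu[d] <- stats::rnorm(1, mean_d, sqrt(1 / prec))
  }
  mu
}

#' Resample one row of the feature matrix
#'
#' One Gibbs update of row `i`: each feature also owned by another row is
#' resampled from its exact conditional (prior odds `m/(N-m)` times the
#' Gaussian likelihood ratio over this row's observed entries); then the
#' row's singleton features are jointly replaced by a Metropolis-Hastings
#' move that proposes `Poisson(alpha/N)` fresh features and accepts via the
#' marginal likelihood with the new weight rows integrated out. Weights for
#' accepted new features are drawn from their exact conditional given this
#' row. All-zero columns are removed. With `prior_only = TRUE` every
#' likelihood term is dropped, so the update targets the IBP prior.
#'
#' @param state An `ibp_state`.
#' @param i Row index to update.
#' @param x_row Length-D numeric vector of this row's standardised scores
#'   (`NA` allowed at unobserved positions).
#' @param mask_row Length-D logical vector of observed positions.
#' @param n_rows Total number of rows N in the data the state describes.
#' @param config A [gibbs_config()] (for the proposal caps).
#' @param prior_only Drop all likelihood terms; default `FALSE`.
#' @return The updated `ibp_state`.
#' @export
sample_row <- function(state, i, x_row, mask_row, n_rows,
                       config = gibbs_config(), prior_only = FALSE) {
  Z <- state$Z; A <- state$A
  sx <- state$sigma_x; sa <- state$sigma_a; alpha <- state$alpha
  d_obs <- which(mask_row)
  x <- x_row[d_obs]
  n_obs <- length(d_obs)
  K <- ncol(Z)
  zi <- if (K > 0) Z[i, ] else numeric(0)
  m_minus <- if (K > 0) colSums(Z) - zi else numeric(0)

  pred <- if (is.null(state$mu)) numeric(n_obs) else state$mu[d_obs]
  if (K > 0 && n_obs > 0) {
    pred <- pred + as.numeric(zi %*% A[, d_obs, drop = FALSE])
  }

  # existing (shared) features: exact Bernoulli conditional
  for (k in seq_len(K)) {
    if (m_minus[k] == 0) next  # singleton of this row; handled below
    log_odds <- log(m_minus[k]) - log(n_rows - m_minus[k])
    if (!prior_only && n_obs > 0) {
      ak <- A[k, d_obs]
      pred_off <- pred - zi[k] * ak
      dll <- (sum((x - pred_off)^2) - sum((x - pred_off - ak)^2)) / (2 * sx^2)
      log_odds <- log_odds + dll
    }
    z_new <- as.numeric(stats::runif(1) < stats::plogis(log_odds))
    if (z_new != zi[k] && !prior_only && n_obs > 0) {
      pred <- pred + (z_new - zi[k]) * A[k, d_obs]
    }
    zi[k] <- z_new
  }

  # replace this row's singleton features via marginal-likelihood MH
  sing <- which(m_minus == 0 & zi == 1)
  k_old <- length(sing)
  # truncated-Poisson proposal: the Poisson prior over the singleton count
  # cancels in the acceptance ratio only if the proposal density is
  # proportional to it on the allowed range
  cap <- config$max_new_features_per_step
  k_new <- sample.int(cap + 1L, 1L,
                      prob = stats::dpois(0:cap, alpha / n_rows)) - 1L
  if (K - k_old + k_new <= config$max_features && (k_old > 0 || k_new > 0)) {
    pred_base <- pred
    if (k_old > 0 && !prior_only && n_obs > 0) {
      pred_base <- pred - colSums(A[sing, d_obs, drop = FALSE])
    }
    if (prior_only || n_obs == 0) {
      log_acc <- 0
    } else {
      # marginal-proposal reversible jump: weight rows of both the current
      # and the proposed singleton set are integrated out, so the ratio is
      # p(x | k_new integrated) / p(x | k_old integrated)
      ll_old <- sum(stats::dnorm(x, pred_base,
                                 sqrt(sx^2 + k_old * sa^2), log = TRUE))
      ll_new <- sum(stats::dnorm(x, pred_base,
                                 sqrt(sx^2 + k_new * sa^2), log = TRUE))
      log_acc <- ll_new - ll_old
    }
    if (log(stats::runif(1)) < log_acc) {
      if (k_old > 0) {
        pred <- pred_base
        zi <- zi[-sing]
        Z <- Z[, -sing, drop = FALSE]
        A <- A[-sing, , drop = FALSE]
        K <- K - k_old
      }
      if (k_new > 0) {
        A_new <- matrix(stats::rnorm(k_new * length(x_row), 0, sa),
                        k_new, length(x_row))
        if (!prior_only && n_obs > 0) {
          # exact conditional of the new weight rows given this row only:
          # precision (J/sx^2 + I/sa^2), shared across observed columns
          prec <- matrix(1 / sx^2, k_new, k_new) + diag(1 / sa^2, k_new)
          u <- chol(prec)
          resid <- x - pred
          for (jj in seq_along(d_obs)) {
            b <- rep(resid[jj] / sx^2, k_new)
            mu <- backsolve(u, backsolve(u, b, transpose = TRUE))
            A_new[, d_obs[jj]] <- mu + backsolve(u, stats::rnorm(k_new))
          }
          pred <- pred + colSums(A_new[, d_obs, drop = FALSE])
        }
        Z <- cbind(Z, matrix(0, nrow(Z), k_new))
        Z[i, K + seq_len(k_new)] <- 1
        A <- rbind(A, A_new)
        zi <- c(zi, rep(1, k_new))
        K <- K + k_new
      }
    }
  }
  Z[i, ] <- zi
  state$Z <- Z; state$A <- A; state$K <- ncol(Z)
  state
}

#' Resample the weight matrix from its conjugate conditional
#'
#' Each column of `A` (one questionnaire item) is drawn from its Gaussian
#' full conditional using only the rows observed at that item: posterior
#' precision `Z_obs' Z_obs / sigma_x^2 + I / sigma_a^2`, posterior mean
#' `precision^-1 Z_obs' x_obs / sigma_x^2`. Items with no observed entries
#' fall back to the `N(0, sigma_a^2)` prior.
#'
#' @param state An `ibp_state` with `K >= 1`.
#' @param values N x D matrix of standardised scores (`NA` at unobserved).
#' @param mask N x D logical observed-entry mask.
#' @return The state with a fresh draw of `A`.
#' @export
sample_weights <- function(state, values, mask) {
  K <- state$K
  if (K < 1L) stop("sample_weights requires at least one active feature")
  sx2 <- state$sigma_x^2; sa2 <- state$sigma_a^2
  A <- state$A
  for (d in seq_len(ncol(values))) {
    rows <- which(mask[, d])
    if (length(rows) == 0L) {
      A[, d] <- stats::rnorm(K, 0, state$sigma_a)
      next
    }
    zo <- state$Z[rows, , drop = FALSE]
    prec <- crossprod(zo) / sx2 + diag(1 / sa2, K)
    u <- chol(prec)
    x_d <- values[rows, d]
    if (!is.null(state$mu)) x_d <- x_d - state$mu[d]
    b <- crossprod(zo, x_d) / sx2
    mu <- backsolve(u, backsolve(u, b, transpose = TRUE))
    A[, d] <- mu + backsolve(u, stats::rnorm(K))
  }
  state$A <- A
  state
}

#' Resample the IBP concentration from its conjugate posterior
#'
#' With a `Gamma(shape, rate)` prior, the conditional given `K` active
#' features over `N` rows is `Gamma(shape + K, rate + H_N)` where `H_N` is
#' the N-th harmonic number.
#'
#' @param state An `ibp_state`.
#' @param n_rows Number of rows N.
#' @param prior `c(shape, rate)` of the Gamma prior; default `c(1, 1)`.
#' @return The state with a fresh `alpha`.
#' @export
resample_alpha <- function(state, n_rows, prior = c(1, 1)) {
  h_n <- sum(1 / seq_len(n_rows))
  state$alpha <- stats::rgamma(1, shape = prior[1] + state$K,
                               rate = prior[2] + h_n)
  state
}

#' Collapsed log-likelihood of complete data given a feature matrix
#'
#' `log p(X | Z)` for the linear-Gaussian model with the weight matrix
#' integrated out analytically. Requires complete data (no mask); it is the
#' enumeration oracle used in tests, not part of the fitting path.
#'
#' @param Z N x K binary matrix (K may be 0).
#' @param X N x D complete data matrix (no `NA`s).
#' @param sigma_x,sigma_a Model standard deviations.
#' @return The collapsed log-likelihood (scalar).
#' @export
collapsed_log_likelihood <- function(Z, X, sigma_x = 0.25, sigma_a = 0.5) {
  if (anyNA(X)) stop("collapsed_log_likelihood requires complete data")
  Z <- as.matrix(Z); X <- as.matrix(X)
  n <- nrow(X); d <- ncol(X); k <- ncol(Z)
  if (k == 0L) {
    return(-n * d / 2 * log(2 * pi) - n * d * log(sigma_x) -
             sum(X^2) / (2 * sigma_x^2))
  }
  m <- crossprod(Z) + diag(sigma_x^2 / sigma_a^2, k)
  u <- chol(m)
  logdet_m <- 2 * sum(log(diag(u)))
  ztx <- crossprod(Z, X)
  w <- backsolve(u, backsolve(u, ztx, transpose = TRUE))
  tr <- sum(X^2) - sum(ztx * w)
  -tr / (2 * sigma_x^2) - n * d / 2 * log(2 * pi) -
    (n - k) * d * log(sigma_x) - k * d * log(sigma_a) - d / 2 * logdet_m
}

#' Canonical (left-ordered) form of a feature matrix
#'
#' Orders columns by ownership count descending, breaking ties by the column
#' pattern read as a binary integer (first row most significant) ascending.
#' Makes feature labelling deterministic across reruns and row permutations.
#'
#' @param Z Binary matrix.
#' @return Integer permutation of the columns (apply as `Z[, ord]`).
#' @export
feature_order <- function(Z) {
  if (ncol(Z) == 0L) return(integer(0))
  keys <- apply(Z, 2, paste0, collapse = "")
  order(-colSums(Z), keys)
}

#' @rdname feature_order
#' @param state An `ibp_state`.
#' @return For `canonicalize_features`: the state with columns of `Z` and
#'   rows of `A` in canonical order.
#' @export
canonicalize_features <- function(state) {
  ord <- feature_order(state$Z)
  state$Z <- state$Z[, ord, drop = FALSE]
  state$A <- state$A[ord, , drop = FALSE]
  state
}

#' Fit the Indian buffet process latent-feature model by Gibbs sampling
#'
#' Alternates full sweeps over the rows of `Z` (see [sample_row()]), a
#' conjugate draw of the weights (see [sample_weights()]) and, optionally, a
#' conjugate draw of the concentration. The Gaussian likelihood is evaluated
#' over observed entries only, so rows produced by a question turn-over
#' design contribute exactly the information they carry and no imputation is
#' performed. Post burn-in, thinned states are retained; the retained state
#' with the highest joint log-probability (`map_state`) is the state used
#' for downstream profiling.
#'
#' @param X An `observation_matrix`, or a list with `values` (N x D numeric,
#'   `NA` at unobserved cells) and optionally `mask`.
#' @param config A [gibbs_config()].
#' @param alpha,sigma_x,sigma_a Model hyperparameters: initial IBP
#'   concentration, observation noise sd and weight prior sd. Defaults 1,
#'   0.25 and 0.5, sized to 32 unit-scaled items.
#' @param intercept Include a per-item mean term `mu` (sampled conjugately,
#'   prior `N(0, sigma_mu^2)`) so that features model deviations from each
#'   item's baseline level rather than absolute unit-scale values; default
#'   `TRUE`. Without it, scores standardised to a strictly positive baseline
#'   force the most prevalent feature to act as a surrogate intercept.
#' @param sigma_mu Prior sd of the intercept term; default 0.5.
#' @param prior_only Run without any likelihood term (samples the IBP prior);
#'   default `FALSE`.
#' @param verbose Print a progress line every 200 sweeps; default `FALSE`.
#' @return An object of class `ibp_posterior`: list with `samples` (retained
#'   `ibp_state`s in canonical feature order), `map_state`, `logp_trace`,
#'   `K_trace`, `alpha_trace` and the `config` echo.
#' @export
run_gibbs <- function(X, config = gibbs_config(), alpha = 1, sigma_x = 0.25,
                      sigma_a = 0.5, intercept = TRUE, sigma_mu = 0.5,
                      prior_only = FALSE, verbose = FALSE) {
  if (inherits(X, "observation_matrix")) {
    values <- X$values; mask <- X$mask
  } else {
    values <- as.matrix(X$values)
    mask <- if (!is.null(X$mask)) X$mask else !is.na(values)
  }
  n <- nrow(values); d <- ncol(values)
  if (n < 2L) stop("need at least 2 rows to fit the model")
  stopifnot(inherits(config, "gibbs_config"))
  set.seed(config$seed)

  state <- ibp_state(matrix(0, n, 0), matrix(0, 0, d), alpha = alpha,
                     sigma_x = sigma_x, sigma_a = sigma_a)
  if (intercept && !prior_only) {
    # start at the observed column means (deterministic)
    vals0 <- values; vals0[!mask] <- NA
    state$mu <- ifelse(colSums(mask) > 0, colMeans(vals0, na.rm = TRUE), 0)
  }
  k0 <- min(config$k_init, config$max_features)
  if (k0 > 0 && !prior_only) {
    z0 <- matrix(stats::rbinom(n * k0, 1, 0.5), n, k0)
    z0 <- z0[, colSums(z0) > 0, drop = FALSE]
    if (ncol(z0) > 0) {
      state$Z <- z0
      state$A <- matrix(0, ncol(z0), d)
      state$K <- ncol(z0)
      state <- sample_weights(state, values, mask)
    }
  }
  n_iter <- config$n_iterations
  logp_trace <- numeric(n_iter)
  k_trace <- integer(n_iter)
  alpha_trace <- numeric(n_iter)
  samples <- list()

  for (it in seq_len(n_iter)) {
    for (i in seq_len(n)) {
      state <- sample_row(state, i, values[i, ], mask[i, ], n, config,
                          prior_only = prior_only)
    }
    if (state$K > 0 && !prior_only) {
      state <- sample_weights(state, values, mask)
    }
    if (!is.null(state$mu)) {
      state$mu <- .sample_intercept(state, values, mask, sigma_mu)
    }
    if (config$resample_alpha) {
      state <- resample_alpha(state, n, config$alpha_prior)
    }
    logp <- if (prior_only) {
      .ibp_log_prior(state$Z, state$alpha)
    } else {
      .joint_logp(state, values, mask, sigma_mu)
    }
    if (!is.finite(logp)) {
      stop("non-finite joint log-probability at iteration ", it)
    }
    logp_trace[it] <- logp
    k_trace[it] <- state$K
    alpha_trace[it] <- state$alpha
    if (it > config$burn_in && (it - config$burn_in) %% config$thin == 0L) {
      s <- canonicalize_features(state)
      s$logp <- logp
      samples[[length(samples) + 1L]] <- s
    }
    if (verbose && it %% 200L == 0L) {
      message(sprintf("iter %d: K = %d, logp = %.1f", it, state$K, logp))
    }
  }
  if (length(samples) == 0L) stop("no samples retained; check burn_in/thin")
  map_idx <- which.max(vapply(samples, `[[`, 0, "logp"))
  structure(list(samples = samples, map_state = samples[[map_idx]],
                 logp_trace = logp_trace, K_trace = k_trace,
                 alpha_trace = alpha_trace, config = config),
            class = "ibp_posterior")
}

#' @export
print.ibp_posterior <- function(x, ...) {
  cat("ibp_posterior:", length(x$samples), "retained states;",
      "MAP K =", x$map_state$K,
      sprintf("(logp = %.1f)\n", x$map_state$logp))
  invisible(x)
}

#' Serialise a fitted posterior to a directory of text files
#'
#' Writes `Z.tsv` and `A.tsv` for the MAP state, `trace.csv`
#' (iteration, K, alpha, logp) and `config.yaml`.
#'
#' @param posterior An `ibp_posterior`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_posterior <- function(posterior, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.table(posterior$map_state$Z, file.path(dir, "Z.tsv"),
                     sep = "\t", row.names = FALSE, col.names = FALSE)
  utils::write.table(posterior$map_state$A, file.path(dir, "A.tsv"),
                     sep = "\t", row.names = FALSE, col.names = FALSE)
  if (!is.null(posterior$map_state$mu)) {
    utils::write.table(posterior$map_state$mu, file.path(dir, "mu.tsv"),
                       sep = "\t", row.names = FALSE, col.names = FALSE)
  }
  utils::write.csv(data.frame(iteration = seq_along(posterior$logp_trace),
                              K = posterior$K_trace,
                              alpha = posterior$alpha_trace,
                              logp = posterior$logp_trace),
                   file.path(dir, "trace.csv"), row.names = FALSE)
  cfg <- unclass(posterior$config)
  cfg$max_features <- if (is.finite(cfg$max_features)) cfg$max_features else "Inf"
  cfg$map_alpha <- posterior$map_state$alpha
  cfg$map_sigma_x <- posterior$map_state$sigma_x
  cfg$map_sigma_a <- posterior$map_state$sigma_a
  yaml::write_yaml(cfg, file.path(dir, "config.yaml"))
  invisible(dir)
}

#' Read a posterior directory written by [write_posterior()]
#'
#' Restores the MAP state and traces (retained per-sample states are not
#' serialised).
#'
#' @param dir Directory path.
#' @return A list with `map_state` (`ibp_state`) and `trace` (data frame).
#' @export
read_posterior <- function(dir) {
  zf <- file.path(dir, "Z.tsv")
  if (!file.exists(zf)) stop("no fitted state found in ", dir)
  Z <- as.matrix(utils::read.table(zf, sep = "\t"))
  if (!all(Z %in% c(0, 1))) stop("corrupt feature matrix in ", zf)
  A <- as.matrix(utils::read.table(file.path(dir, "A.tsv"), sep = "\t"))
  cfg <- yaml::read_yaml(file.path(dir, "config.yaml"))
  state <- ibp_state(Z, A, alpha = cfg$map_alpha, sigma_x = cfg$map_sigma_x,
                     sigma_a = cfg$map_sigma_a)
  muf <- file.path(dir, "mu.tsv")
  if (file.exists(muf)) {
    state$mu <- utils::read.table(muf, sep = "\t")[[1]]
  }
  list(map_state = state,
       trace = utils::read.csv(file.path(dir, "trace.csv")))
}
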