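#' Write a simulated EMA stream to disk
#'
#' Runs [simulate_ema_stream()] and writes `ema.csv` (long-format records),
#' `truth.csv` (per patient-day ground-truth profile) and a `manifest.yaml`
#' echoing the seed and row counts.
#'
#' @param out_dir Output directory (created if needed).
#' @param seed Integer RNG seed.
#' @param cohort A [cohort_config()].
#' @param schema An `ema_schema`.
#' @param schedule A [period_schedule()].
#' @return Invisibly, the list returned by [simulate_ema_stream()].
#' @export
cmd_simulate <- function(out_dir, seed = 1L, cohort = cohort_config(),
                         schema = default_schema(),
                         schedule = period_schedule()) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  sim <- simulate_ema_stream(cohort, schema = schema, schedule = schedule,
                             seed = seed)
  write_ema_table(sim$records, file.path(out_dir, "ema.csv"))
  truth <- sim$truth
  truth <- data.frame(row_id = seq_len(nrow(truth)), truth)
  utils::write.csv(truth, file.path(out_dir, "truth.csv"), row.names = FALSE)
  write_schema_config(schema, file.path(out_dir, "schema.yaml"), schedule)
  yaml::write_yaml(list(
    step = "simulate", seed = as.integer(seed),
    package_version = as.character(utils::packageVersion("emaprofiles")),
    n_records = nrow(sim$records),
    n_sessions = as.list(table(sim$truth$period))
  ), file.path(out_dir, "manifest.yaml"))
  invisible(sim)
}

#' Fit the latent-feature model to an EMA table on disk
#'
#' Reads and validates the long-format table, assembles the masked
#' observation matrix, runs the Gibbs sampler and serialises the posterior.
#'
#' @param ema_csv Path to a long-format EMA table.
#' @param out_dir Output directory for the posterior files.
#' @param schema An `ema_schema`.
#' @param schedule A [period_schedule()].
#' @param config A [gibbs_config()].
#' @param ... Passed to [run_gibbs()] (e.g. `sigma_x`, `verbose`).
#' @return Invisibly, a list with the `observation_matrix` and the fitted
#'   `ibp_posterior`.
#' @export
cmd_fit <- function(ema_csv, out_dir, schema = default_schema(),
                    schedule = period_schedule(), config = gibbs_config(),
                    ...) {
  records <- read_ema_table(ema_csv, schema)
  if (nrow(records) == 0L) stop("EMA table is empty: ", ema_csv)
  obs <- build_observation_matrix(records, schema, schedule)
  post <- run_gibbs(obs, config, ...)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_posterior(post, out_dir)
  utils::write.csv(obs$row_meta, file.path(out_dir, "row_meta.csv"),
                   row.names = FALSE)
  yaml::write_yaml(list(
    step = "fit", seed = config$seed,
    package_version = as.character(utils::packageVersion("emaprofiles")),
    input = basename(ema_csv),
    input_md5 = unname(tools::md5sum(ema_csv)),
    n_rows = nrow(obs$values), map_K = post$map_state$K,
    final_logp = post$map_state$logp
  ), file.path(out_dir, "manifest.yaml"))
  invisible(list(obs = obs, posterior = post))
}

#' Profile and compare a fitted posterior across periods
#'
#' Loads a serialised posterior, derives profile labels, signatures and the
#' per-profile period contrasts, and writes the report artifacts.
#'
#' @param fit_dir Directory written by [cmd_fit()].
#' @param ema_csv The EMA table the posterior was fitted to (for the
#'   signature computation).
#' @param out_dir Output directory; defaults to `fit_dir`.
#' @param schema An `ema_schema`.
#' @param schedule A [period_schedule()].
#' @param top_m Profiles reported individually; default 4.
#' @return Invisibly, a list with `assignment`, `signatures` and `report`.
#' @export
cmd_compare <- function(fit_dir, ema_csv, out_dir = fit_dir,
                        schema = default_schema(),
                        schedule = period_schedule(), top_m = NULL) {
  fit <- read_posterior(fit_dir)
  records <- read_ema_table(ema_csv, schema)
  obs <- build_observation_matrix(records, schema, schedule)
  if (nrow(obs$values) != nrow(fit$map_state$Z)) {
    stop("posterior in ", fit_dir, " was fitted to ", nrow(fit$map_state$Z),
         " rows but the table yields ", nrow(obs$values))
  }
  assignment <- assign_profiles(fit$map_state, obs)
  signatures <- feature_signature(assignment, obs)
  report <- build_report(assignment, obs$row_meta$period, top_m = top_m)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_profile_artifacts(assignment, signatures, out_dir)
  utils::write.csv(report, file.path(out_dir, "period_contrasts.csv"),
                   row.names = FALSE)
  invisible(list(assignment = assignment, signatures = signatures,
                 report = report))
}

#' Run the whole pipeline: simulate, fit, profile, compare
#'
#' End-to-end driver over the package's modules with a single seed: generate
#' a synthetic EMA stream, assemble the masked observation matrix, fit the
#' latent-feature model, assign profiles and contrast their prevalence
#' between the two periods. All artifacts land under `out_dir`
#' (`data/`, `fit/`).
#'
#' @param out_dir Output directory.
#' @param seed Integer seed controlling both generation and fitting.
#' @param cohort A [cohort_config()].
#' @param schema An `ema_schema`.
#' @param schedule A [period_schedule()].
#' @param config A [gibbs_config()]; its `seed` is overridden by `seed`.
#' @param ... Passed to [run_gibbs()].
#' @return Invisibly, a list with `sim`, `obs`, `posterior`, `assignment`,
#'   `signatures`, `report`.
#' @export
run_pipeline <- function(out_dir, seed = 1L, cohort = cohort_config(),
                         schema = default_schema(),
                         schedule = period_schedule(),
                         config = gibbs_config(), ...) {
  config$seed <- as.integer(seed)
  data_dir <- file.path(out_dir, "data")
  fit_dir <- file.path(out_dir, "fit")
  sim <- cmd_simulate(data_dir, seed = seed, cohort = cohort, schema = schema,
                      schedule = schedule)
  fit <- cmd_fit(file.path(data_dir, "ema.csv"), fit_dir, schema = schema,
                 schedule = schedule, config = config, ...)
  cmp <- cmd_compare(fit_dir, file.path(data_dir, "ema.csv"), schema = schema,
                     schedule = schedule)
  invisible(list(sim = sim, obs = fit$obs, posterior = fit$posterior,
                 assignment = cmp$assignment, signatures = cmp$signatures,
                 report = cmp$report))
}

#' Match recovered profiles to generating templates
#'
#' Greedy best-match alignment between recovered profile signatures and the
#' positive-probability vectors of the generating templates, by smallest
#' root-mean-square difference over the items observed in the signature
#' (a flat template, e.g. the all-low baseline profile, has no defined
#' Pearson correlation, so distances drive the matching). Per-pair
#' correlations are reported where defined, and the correlation pooled over
#' all matched template-item pairs is attached as the `pooled_correlation`
#' attribute.
#'
#' @param signatures P x D matrix from [feature_signature()] (`NA` allowed).
#' @param templates List of `profile_template`s.
#' @return Data frame with one row per template: `template`, the matched
#'   `profile` row index, the pair's `rmse` and its `correlation`
#'   (`NA` when either vector is constant).
#' @export
match_profiles_to_templates <- function(signatures, templates) {
  tpl <- vapply(templates, `[[`, numeric(ncol(signatures)), "positive_prob")
  np <- nrow(signatures); nt <- length(templates)
  rmse <- matrix(Inf, np, nt)
  cors <- matrix(NA_real_, np, nt)
  for (i in seq_len(np)) {
    ok <- !is.na(signatures[i, ])
    if (sum(ok) < 3) next
    for (j in seq_len(nt)) {
      diffs <- signatures[i, ok] - tpl[ok, j]
      rmse[i, j] <- sqrt(mean(diffs^2))
      if (stats::sd(signatures[i, ok]) > 0 && stats::sd(tpl[ok, j]) > 0) {
        cors[i, j] <- stats::cor(signatures[i, ok], tpl[ok, j])
      }
    }
  }
  out <- data.frame(template = seq_len(nt), profile = NA_integer_,
                    rmse = NA_real_, correlation = NA_real_)
  free <- rep(TRUE, np)
  remaining <- seq_len(nt)
  while (length(remaining) > 0 && any(free)) {
    sub <- rmse[free, remaining, drop = FALSE]
    if (all(!is.finite(sub))) break
    best <- which(sub == min(sub), arr.ind = TRUE)[1, ]
    prof <- which(free)[best[1]]
    tmpl <- remaining[best[2]]
    out$profile[tmpl] <- prof
    out$rmse[tmpl] <- rmse[prof, tmpl]
    out$correlation[tmpl] <- cors[prof, tmpl]
    free[prof] <- FALSE
    remaining <- setdiff(remaining, tmpl)
  }
  sig_all <- tpl_all <- numeric(0)
  for (j in which(!is.na(out$profile))) {
    ok <- !is.na(signatures[out$profile[j], ])
    sig_all <- c(sig_all, signatures[out$profile[j], ok])
    tpl_all <- c(tpl_all, tpl[ok, j])
  }
  attr(out, "pooled_correlation") <-
    if (length(sig_all) >= 3) stats::cor(sig_all, tpl_all) else NA_real_
  out
}
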