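#' Per-profile 2x2 period contingency table
#'
#' Cross-tabulates membership in one profile against the two study periods.
#'
#' @param labels Integer profile label per observation.
#' @param period_labels Character period per observation
#'   (`"pre_lockdown"` / `"lockdown"`).
#' @param profile_id The profile to dichotomise on, or a vector of profile
#'   ids to pool (e.g. the rare remainder).
#' @return 2x2 integer matrix, rows `pre_lockdown` / `lockdown`, columns
#'   `in_profile` / `not_in_profile`.
#' @export
contingency_table <- function(labels, period_labels, profile_id) {
  stopifnot(length(labels) == length(period_labels))
  if (!all(profile_id %in% labels)) {
    missing <- setdiff(profile_id, labels)
    stop("unknown profile id(s): ", paste(missing, collapse = ", "))
  }
  periods <- c("pre_lockdown", "lockdown")
  if (!all(period_labels %in% periods)) stop("unrecognised period label")
  inp <- labels %in% profile_id
  tab <- matrix(0L, 2, 2,
                dimnames = list(periods, c("in_profile", "not_in_profile")))
  for (r in 1:2) {
    sel <- period_labels == periods[r]
    tab[r, ] <- c(sum(inp & sel), sum(!inp & sel))
  }
  if (any(rowSums(tab) == 0L)) {
    stop("degenerate margin: a period has no observations")
  }
  tab
}

#' Continuity-corrected chi-squared test for a 2x2 table
#'
#' Yates-corrected statistic
#' `n * (max(0, |ad - bc| - n/2))^2 / ((a+b)(c+d)(a+c)(b+d))` with the
#' correction floored at zero so the statistic is never negative, and a
#' two-sided p-value from the upper tail of the chi-squared distribution
#' with 1 degree of freedom.
#'
#' @param table 2x2 matrix of non-negative counts with all four margins
#'   positive.
#' @return List with `chi2` and `p_value`.
#' @export
#' @examples
#' yates_chi_square(matrix(c(413, 547, 113, 101), 2, 2, byrow = TRUE))
yates_chi_square <- function(table) {
  table <- as.matrix(table)
  storage.mode(table) <- "double"
  stopifnot(all(dim(table) == c(2, 2)), all(table >= 0))
  if (any(rowSums(table) == 0) || any(colSums(table) == 0)) {
    stop("degenerate table: a margin is zero")
  }
  n <- sum(table)
  a <- table[1, 1]; b <- table[1, 2]; c_ <- table[2, 1]; d <- table[2, 2]
  num <- max(0, abs(a * d - b * c_) - n / 2)
  chi2 <- n * num^2 / (sum(table[1, ]) * sum(table[2, ]) *
                         sum(table[, 1]) * sum(table[, 2]))
  list(chi2 = chi2, p_value = stats::pchisq(chi2, df = 1, lower.tail = FALSE))
}

#' Uncorrected Pearson chi-squared statistic for a 2x2 table
#'
#' @param table 2x2 count matrix with positive margins.
#' @return The Pearson statistic (no continuity correction).
#' @export
pearson_chi_square <- function(table) {
  table <- as.matrix(table)
  storage.mode(table) <- "double"
  n <- sum(table)
  a <- table[1, 1]; b <- table[1, 2]; c_ <- table[2, 1]; d <- table[2, 2]
  n * (a * d - b * c_)^2 / (sum(table[1, ]) * sum(table[2, ]) *
                              sum(table[, 1]) * sum(table[, 2]))
}

#' Relative change between two prevalences
#'
#' `100 * (p_lockdown - p_pre) / p_pre`, the signed percent change of the
#' lockdown prevalence relative to the pre-lockdown prevalence.
#'
#' @param p_pre,p_lockdown Prevalences (any common scale, e.g. percent).
#' @return Signed percent change.
#' @export
#' @examples
#' percent_change(43.0, 52.8)  # +22.8
percent_change <- function(p_pre, p_lockdown) {
  if (any(p_pre == 0)) stop("percent change undefined for zero baseline")
  100 * (p_lockdown - p_pre) / p_pre
}

#' Format a percent change with its direction word
#'
#' @param change Signed percent change.
#' @return E.g. `"22.8% increase"` or `"42.1% decrease"`.
#' @export
format_percent_change <- function(change) {
  word <- ifelse(change >= 0, "increase", "decrease")
  sprintf("%.1f%% %s", abs(change), word)
}

#' Exact (Clopper-Pearson) binomial confidence interval
#'
#' Bounds obtained by inverting the binomial tails via beta quantiles:
#' lower `qbeta(a/2, x, n - x + 1)`, upper `qbeta(1 - a/2, x + 1, n - x)`,
#' with the conventions lower = 0 when `x = 0` and upper = 100 when `x = n`.
#'
#' @param x Number of successes.
#' @param n Number of trials.
#' @param level Confidence level in (0, 1); default 0.95.
#' @return Named numeric `c(lower, upper)` as percentages.
#' @export
#' @examples
#' clopper_pearson_ci(7, 960)  # approx c(0.3, 1.5)
clopper_pearson_ci <- function(x, n, level = 0.95) {
  stopifnot(level > 0, level < 1, n >= 1)
  if (x < 0 || x > n) stop("x must lie in 0..n")
  a <- 1 - level
  lower <- if (x == 0) 0 else stats::qbeta(a / 2, x, n - x + 1)
  upper <- if (x == n) 1 else stats::qbeta(1 - a / 2, x + 1, n - x)
  c(lower = 100 * lower, upper = 100 * upper)
}

#' Reconstruct integer counts from printed prevalences
#'
#' Rounds `pct * total / 100` half away from zero, the convention under
#' which published period prevalences and totals yield integer tables.
#'
#' @param total Period row count.
#' @param pct Prevalence in percent.
#' @return Integer count.
#' @export
counts_from_prevalence <- function(total, pct) {
  x <- pct * total / 100
  as.integer(sign(x) * floor(abs(x) + 0.5))
}

#' Full period contrast from printed prevalences
#'
#' Convenience wrapper: reconstructs each profile's 2x2 table from period
#' totals and prevalence percentages (see [counts_from_prevalence()]) and
#' runs the continuity-corrected test and percent change.
#'
#' @param n_pre,n_lockdown Period totals.
#' @param prev_pre,prev_lockdown Equal-length numeric vectors of per-profile
#'   prevalences in percent.
#' @return Data frame with one row per profile: reconstructed counts,
#'   `chi2`, `p_value`, `pct_change`.
#' @export
contrast_from_prevalences <- function(n_pre, n_lockdown, prev_pre,
                                      prev_lockdown) {
  stopifnot(length(prev_pre) == length(prev_lockdown))
  out <- lapply(seq_along(prev_pre), function(j) {
    a <- counts_from_prevalence(n_pre, prev_pre[j])
    c2 <- counts_from_prevalence(n_lockdown, prev_lockdown[j])
    tab <- matrix(c(a, n_pre - a, c2, n_lockdown - c2), 2, 2, byrow = TRUE)
    ch <- yates_chi_square(tab)
    data.frame(profile = j, n_in_pre = a, n_in_lockdown = c2,
               prev_pre_pct = prev_pre[j], prev_lockdown_pct = prev_lockdown[j],
               chi2 = ch$chi2, p_value = ch$p_value,
               pct_change = percent_change(prev_pre[j], prev_lockdown[j]))
  })
  do.call(rbind, out)
}

#' Per-profile period comparison report
#'
#' For each of the leading profiles, builds the 2x2 table against the two
#' periods, runs the continuity-corrected chi-squared test and computes the
#' prevalence percent change. Profiles beyond `top_m` are pooled into a
#' single "rare" row whose pre-lockdown prevalence receives an exact
#' binomial confidence interval.
#'
#' @param assignment A [assign_profiles()] result.
#' @param period_labels Character period label per observation, aligned with
#'   `assignment$labels`.
#' @param top_m Number of profiles reported individually; default
#'   `min(4, P)`.
#' @param level Confidence level for the rare-pool interval; default 0.95.
#' @return An object of class `period_contrast_report`: a data frame with
#'   columns `profile, n_pre, n_lock, prev_pre_pct, prev_lock_pct, chi2,
#'   p_value, pct_change, ci_lower_pct, ci_upper_pct` (interval only on the
#'   rare row).
#' @export
build_report <- function(assignment, period_labels, top_m = NULL,
                         level = 0.95) {
  stopifnot(inherits(assignment, "profile_assignment"))
  labels <- assignment$labels
  if (length(period_labels) != length(labels)) {
    stop("period labels and assignment are inconsistent")
  }
  periods <- unique(period_labels)
  if (length(periods) < 2L) stop("need both periods to compare")
  p <- length(assignment$prevalence)
  if (is.null(top_m)) top_m <- min(4L, p)
  n_pre <- sum(period_labels == "pre_lockdown")
  n_lock <- sum(period_labels == "lockdown")

  one_row <- function(ids, name) {
    a <- sum(labels %in% ids & period_labels == "pre_lockdown")
    c2 <- sum(labels %in% ids & period_labels == "lockdown")
    tab <- matrix(c(a, n_pre - a, c2, n_lock - c2), 2, 2, byrow = TRUE)
    prev_pre <- 100 * a / n_pre
    prev_lock <- 100 * c2 / n_lock
    ch <- tryCatch(yates_chi_square(tab),
                   error = function(e) list(chi2 = NA_real_, p_value = NA_real_))
    data.frame(profile = name, n_pre = a, n_lock = c2,
               prev_pre_pct = prev_pre, prev_lock_pct = prev_lock,
               chi2 = ch$chi2, p_value = ch$p_value,
               pct_change = if (prev_pre > 0) {
                 percent_change(prev_pre, prev_lock)
               } else NA_real_,
               ci_lower_pct = NA_real_, ci_upper_pct = NA_real_)
  }
  rows <- lapply(seq_len(top_m), function(j) one_row(j, as.character(j)))
  if (p > top_m) {
    rare <- one_row(seq.int(top_m + 1L, p), "rare")
    ci <- clopper_pearson_ci(rare$n_pre, n_pre, level)
    rare$ci_lower_pct <- ci[["lower"]]
    rare$ci_upper_pct <- ci[["upper"]]
    rows <- c(rows, list(rare))
  }
  out <- do.call(rbind, rows)
  class(out) <- c("period_contrast_report", class(out))
  attr(out, "n_pre") <- n_pre
  attr(out, "n_lock") <- n_lock
  out
}

#' @export
print.period_contrast_report <- function(x, ...) {
  cat(sprintf("Period comparison: %d pre-lockdown vs %d lockdown observations\n",
              attr(x, "n_pre"), attr(x, "n_lock")))
  for (i in seq_len(nrow(x))) {
    pv <- if (is.na(x$p_value[i])) {
      "p = NA"
    } else if (x$p_value[i] < 0.001) {
      "p < 0.001"
    } else {
      sprintf("p = %.3f", x$p_value[i])
    }
    line <- sprintf("  profile %s: %.1f%% -> %.1f%%", x$profile[i],
                    x$prev_pre_pct[i], x$prev_lock_pct[i])
    if (!is.na(x$pct_change[i])) {
      line <- paste0(line, sprintf(" (%s)", format_percent_change(x$pct_change[i])))
    }
    if (!is.na(x$chi2[i])) {
      line <- paste0(line, sprintf("; chi2 = %.2f, %s", x$chi2[i], pv))
    }
    if (!is.na(x$ci_lower_pct[i])) {
      line <- paste0(line, sprintf("; 95%% CI %.1f-%.1f%%",
                                   x$ci_lower_pct[i], x$ci_upper_pct[i]))
    }
    cat(line, "\n")
  }
  invisible(x)
}
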