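#' Latent risk-profile template
#'
#' A template describes how observation vectors are generated under one latent
#' profile: a 32-vector of mean standardised severities, the response noise,
#' and the implied probability that each item scores positive (standardised
#' score at or above the binarization threshold). Responses are drawn as
#' Gaussian noise around the severity mean and clipped to \[0, 1\], so the
#' positive probability is `1 - pnorm((threshold - mean) / noise_sd)`.
#'
#' @param profile_id Integer identifier (>= 1).
#' @param severity_means Numeric vector of unit-interval means, one per item.
#' @param noise_sd Response noise standard deviation on the standardised
#'   scale; default 0.15.
#' @param threshold Binarization threshold used for `positive_prob`;
#'   default 0.5.
#' @return An object of class `profile_template` with fields `profile_id`,
#'   `severity_means`, `positive_prob`, `noise_sd`.
#' @export
profile_template <- function(profile_id, severity_means, noise_sd = 0.15,
                             threshold = 0.5) {
  stopifnot(profile_id >= 1, all(severity_means >= 0 & severity_means <= 1),
            noise_sd > 0)
  structure(list(profile_id = as.integer(profile_id),
                 severity_means = as.numeric(severity_means),
                 positive_prob = 1 - stats::pnorm((threshold - severity_means) / noise_sd),
                 noise_sd = noise_sd),
            class = "profile_template")
}

#' Default four risk-profile templates
#'
#' The default latent structure is compositional: two latent symptom axes —
#' a death-wish/somatic axis (wish to die, loss of wish to live, sleep
#' problems, decreased appetite) and a negative-emotions axis — combine into
#' four profiles. Profile 1 activates neither axis (low severity on all 32
#' items), Profile 2 activates the death-wish/somatic axis only, Profile 3
#' the negative-emotions axis only, and Profile 4 both. This reproduces the
#' qualitative signature ordering reported for such cohorts: Profiles 2 and 4
#' high on wish-to-die, sleep and appetite items; Profiles 3 and 4 high on
#' negative feelings; Profile 1 low everywhere.
#'
#' @param schema An `ema_schema` providing domain membership; default
#'   [default_schema()].
#' @param base,elevated Severity means (standardised scale) for unaffected and
#'   affected items; defaults 0.18 and 0.78.
#' @param noise_sd Response noise sd passed to [profile_template()].
#' @return List of four `profile_template`s.
#' @export
default_profile_templates <- function(schema = default_schema(), base = 0.18,
                                      elevated = 0.78, noise_sd = 0.15) {
  d <- length(schema)
  somatic <- c(domain_items(schema, "wish_to_die_live"),
               domain_items(schema, "sleep"), domain_items(schema, "appetite"))
  affective <- domain_items(schema, "negative_feelings")
  mk <- function(id, on) {
    m <- rep(base, d); m[on] <- elevated
    profile_template(id, m, noise_sd = noise_sd)
  }
  list(mk(1L, integer()), mk(2L, somatic), mk(3L, affective),
       mk(4L, c(somatic, affective)))
}

#' Low-distinctiveness rare-profile templates
#'
#' Templates for the residual profile mass: each elevates a small contiguous
#' block of items only mildly, so rows drawn from them are hard to separate
#' from the dominant profiles.
#'
#' @param schema An `ema_schema`.
#' @param n Number of rare templates (1-4); default 4.
#' @param base,bump Baseline mean and mild elevation; defaults 0.18 and 0.55.
#' @param noise_sd Response noise sd.
#' @return List of `profile_template`s with ids `5, 6, ...`.
#' @export
rare_profile_templates <- function(schema = default_schema(), n = 4L,
                                   base = 0.18, bump = 0.55, noise_sd = 0.15) {
  stopifnot(n >= 1L, n <= 4L)
  d <- length(schema)
  lapply(seq_len(n), function(j) {
    m <- rep(base, d)
    m[((j - 1L) * 8L + 1L):(j * 8L)] <- bump
    profile_template(4L + j, m, noise_sd = noise_sd)
  })
}

#' Default period-specific profile mixtures
#'
#' Profile prevalence weights for the two study periods, in the order
#' (Profile 1, Profile 2, Profile 3, Profile 4, rare remainder). The defaults
#' encode the study conditions the generator emulates: pre-lockdown
#' 43.0 / 17.8 / 26.7 / 11.8 % with a 0.7% residual, lockdown
#' 52.8 / 10.3 / 34.6 / 2.3 % with no residual.
#'
#' @return List with numeric elements `pre` and `lockdown`, each summing to 1.
#' @export
default_mixtures <- function() {
  list(pre = c(0.430, 0.178, 0.267, 0.118, 0.007),
       lockdown = c(0.528, 0.103, 0.346, 0.023, 0.000))
}

#' Cohort and sampling-design configuration for the generator
#'
#' Defaults mirror the emulated cohort: 36 patients, 86.1% women, mean age
#' 41.7 (sd 16.3) years, mean 1.1 prior suicide attempts; 2-4 random
#' questions per day prompted between 10:00 and 22:00; per-period target row
#' counts 960 (pre-lockdown) and 214 (lockdown) reached by uniform thinning
#' of patient-days.
#'
#' @param n_patients Number of patients; default 36.
#' @param pct_female Percentage of women; default 86.1.
#' @param age_mean,age_sd Age distribution in years (truncated at 18);
#'   defaults 41.7 and 16.3.
#' @param prior_attempts_mean Poisson mean of previous attempts; default 1.1.
#' @param mixture_pre,mixture_lockdown Profile weight vectors
#'   (4 profiles + remainder); defaults from [default_mixtures()].
#' @param questions_per_day_min,questions_per_day_max Range of the daily
#'   question count drawn per patient-day; defaults 2 and 4.
#' @param prompt_window_hours Numeric `c(start, end)` in hours of day;
#'   default `c(10, 22)`.
#' @param target_rows Named vector `c(pre = ..., lockdown = ...)` of
#'   post-thinning observation-vector counts; defaults 960 and 214.
#' @param noise_sd Response noise sd; default 0.15.
#' @param sticky Probability that a patient keeps the previous day's profile
#'   instead of redrawing from the mixture; default 0 (profiles i.i.d. per
#'   patient-day).
#' @return An object of class `cohort_config`.
#' @export
cohort_config <- function(n_patients = 36L, pct_female = 86.1,
                          age_mean = 41.7, age_sd = 16.3,
                          prior_attempts_mean = 1.1,
                          mixture_pre = default_mixtures()$pre,
                          mixture_lockdown = default_mixtures()$lockdown,
                          questions_per_day_min = 2L,
                          questions_per_day_max = 4L,
                          prompt_window_hours = c(10, 22),
                          target_rows = c(pre = 960L, lockdown = 214L),
                          noise_sd = 0.15, sticky = 0) {
  stopifnot(n_patients >= 1L,
            abs(sum(mixture_pre) - 1) < 1e-9,
            abs(sum(mixture_lockdown) - 1) < 1e-9,
            all(mixture_pre >= 0), all(mixture_lockdown >= 0),
            questions_per_day_min >= 1L,
            questions_per_day_min <= questions_per_day_max,
            length(prompt_window_hours) == 2L,
            prompt_window_hours[1] < prompt_window_hours[2],
            sticky >= 0, sticky <= 1)
  structure(list(n_patients = as.integer(n_patients), pct_female = pct_female,
                 age_mean = age_mean, age_sd = age_sd,
                 prior_attempts_mean = prior_attempts_mean,
                 mixture_pre = mixture_pre,
                 mixture_lockdown = mixture_lockdown,
                 questions_per_day_min = as.integer(questions_per_day_min),
                 questions_per_day_max = as.integer(questions_per_day_max),
                 prompt_window_hours = prompt_window_hours,
                 target_rows = target_rows, noise_sd = noise_sd,
                 sticky = sticky),
            class = "cohort_config")
}

# deterministic per-patient sub-seed below 2^31
.patient_seed <- function(seed, patient_idx) {
  as.integer((as.numeric(seed) * 7919 + patient_idx * 104729) %% 2147483647)
}

#' Simulate an EMA response stream with known latent structure
#'
#' For every patient and study day a latent profile is drawn from the
#' period's mixture (optionally sticky across days), a uniform 2-4 distinct
#' questions are selected from the 32-item pool, prompt times are drawn
#' uniformly in the 10:00-22:00 window, and each answer is the template's
#' severity mean plus Gaussian noise, clipped to \[0, 1\] and mapped back to
#' the item's raw scale. Patient-days are then thinned uniformly per period
#' to the target row counts, emulating partial compliance. Each patient has
#' an RNG stream derived from `(seed, patient)`, so an individual patient's
#' data are reproducible.
#'
#' @param cohort A [cohort_config()].
#' @param templates List of `profile_template`s for the dominant profiles;
#'   default [default_profile_templates()].
#' @param schema An `ema_schema`; default [default_schema()].
#' @param schedule A [period_schedule()] defining the two periods.
#' @param seed Integer RNG seed.
#' @param rare_templates Templates receiving the remainder mixture mass;
#'   default [rare_profile_templates()]. Ignored when the mixtures carry no
#'   remainder entry.
#' @return List with `records` (long-format data frame:
#'   `patient_id, timestamp, question_id, raw_value`) and `truth` (one row
#'   per kept patient-day: `patient_id, date, period, true_profile`).
#' @export
#' @examples
#' sim <- simulate_ema_stream(cohort_config(target_rows = c(pre = 40, lockdown = 10)),
#'                            seed = 1)
#' table(sim$truth$period)
simulate_ema_stream <- function(cohort = cohort_config(),
                                templates = default_profile_templates(schema),
                                schema = default_schema(),
                                schedule = period_schedule(), seed = 1L,
                                rare_templates = rare_profile_templates(schema)) {
  stopifnot(inherits(cohort, "cohort_config"), inherits(schema, "ema_schema"))
  n_main <- length(templates)
  has_rest <- length(cohort$mixture_pre) == n_main + 1L
  if (!has_rest && length(cohort$mixture_pre) != n_main) {
    stop("mixture length must equal the number of templates, ",
         "optionally plus one remainder entry")
  }
  all_templates <- if (has_rest) c(templates, rare_templates) else templates
  n_rare <- length(all_templates) - n_main
  expand <- function(mix) {
    if (!has_rest) return(mix)
    c(mix[seq_len(n_main)], rep(mix[n_main + 1L] / n_rare, n_rare))
  }
  mix_by_period <- list(pre_lockdown = expand(cohort$mixture_pre),
                        lockdown = expand(cohort$mixture_lockdown))

  days <- c(seq(schedule$pre_start, schedule$pre_end, by = "day"),
            seq(schedule$lockdown_start, schedule$lockdown_end, by = "day"))
  day_period <- period_of_date(days, schedule)
  d <- length(schema)
  win <- cohort$prompt_window_hours * 3600

  per_patient <- vector("list", cohort$n_patients)
  truth_list <- vector("list", cohort$n_patients)
  for (p in seq_len(cohort$n_patients)) {
    set.seed(.patient_seed(seed, p))
    pid <- sprintf("P%03d", p)
    prev_profile <- NA_integer_
    nq <- sample(cohort$questions_per_day_min:cohort$questions_per_day_max,
                 length(days), replace = TRUE)
    profs <- integer(length(days))
    for (i in seq_along(days)) {
      if (!is.na(prev_profile) && cohort$sticky > 0 &&
          stats::runif(1) < cohort$sticky) {
        profs[i] <- prev_profile
      } else {
        profs[i] <- sample.int(length(all_templates), 1L,
                               prob = mix_by_period[[day_period[i]]])
      }
      prev_profile <- profs[i]
    }
    tot <- sum(nq)
    qidx <- integer(tot); secs <- numeric(tot); day_of <- integer(tot)
    pos <- 0L
    for (i in seq_along(days)) {
      sel <- sample.int(d, nq[i])
      idx <- pos + seq_len(nq[i])
      qidx[idx] <- sel
      secs[idx] <- stats::runif(nq[i], win[1], win[2])
      day_of[idx] <- i
      pos <- pos + nq[i]
    }
    mu <- vapply(all_templates, function(t) t$severity_means, numeric(d))
    score <- pmin(pmax(mu[cbind(qidx, profs[day_of])] +
                         stats::rnorm(tot, 0, cohort$noise_sd), 0), 1)
    raw <- numeric(tot)
    for (j in unique(qidx)) {
      sel <- qidx == j
      raw[sel] <- unstandardize_response(score[sel], schema$items[[j]])
    }
    per_patient[[p]] <- data.frame(
      patient_id = pid,
      timestamp = as.POSIXct(days[day_of], tz = "UTC") + round(secs / 60) * 60,
      question_id = schema$question_ids[qidx],
      raw_value = round(raw, 4))
    truth_list[[p]] <- data.frame(patient_id = pid, date = days,
                                  period = day_period,
                                  true_profile = as.integer(profs))
  }
  records <- do.call(rbind, per_patient)
  truth <- do.call(rbind, truth_list)

  # uniform compliance thinning per period to the target row counts
  set.seed(.patient_seed(seed, 0L))
  keep <- logical(nrow(truth))
  for (per in c("pre_lockdown", "lockdown")) {
    tgt <- unname(cohort$target_rows[[if (per == "pre_lockdown") "pre" else "lockdown"]])
    idx <- which(truth$period == per)
    if (length(idx) < tgt) {
      warning("only ", length(idx), " patient-days available in ", per,
              "; target ", tgt, " not reached")
      keep[idx] <- TRUE
    } else {
      keep[sample(idx, tgt)] <- TRUE
    }
  }
  truth <- truth[keep, , drop = FALSE]
  rownames(truth) <- NULL
  key <- paste(records$patient_id, as.Date(records$timestamp, tz = "UTC"))
  records <- records[key %in% paste(truth$patient_id, truth$date), , drop = FALSE]
  rownames(records) <- NULL
  list(records = records, truth = truth)
}

#' Generate a synthetic patient demographics table
#'
#' @param cohort A [cohort_config()].
#' @param seed Integer RNG seed.
#' @return Data frame with one row per patient: `patient_id`, `age` (normal,
#'   truncated at 18), `sex` (`"F"`/`"M"`), `prior_attempts` (Poisson).
#' @export
generate_demographics <- function(cohort = cohort_config(), seed = 1L) {
  stopifnot(inherits(cohort, "cohort_config"))
  set.seed(seed)
  n <- cohort$n_patients
  age <- stats::rnorm(n, cohort$age_mean, cohort$age_sd)
  while (any(age < 18)) {
    i <- age < 18
    age[i] <- stats::rnorm(sum(i), cohort$age_mean, cohort$age_sd)
  }
  data.frame(patient_id = sprintf("P%03d", seq_len(n)),
             age = age,
             sex = ifelse(stats::runif(n) < cohort$pct_female / 100, "F", "M"),
             prior_attempts = stats::rpois(n, cohort$prior_attempts_mean))
}
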