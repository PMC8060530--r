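#' Questionnaire item specification
#'
#' A single EMA item: its identifier, the symptom domain it belongs to, the
#' raw response range, and its polarity. Polarity `"worse_high"` means a high
#' raw answer indicates a worse state (e.g. "wish to die"); `"worse_low"`
#' means a high raw answer indicates a better state (e.g. "wish to live",
#' sleep quality), and standardisation flips it so that after scaling the
#' highest value always expresses the worse state.
#'
#' @param question_id Short character key, unique within a schema.
#' @param domain One of `"wish_to_die_live"`, `"sleep"`, `"negative_feelings"`,
#'   `"appetite"`.
#' @param min_raw,max_raw Numeric bounds of the raw response scale
#'   (`max_raw > min_raw`).
#' @param polarity `"worse_high"` (default) or `"worse_low"`.
#' @return An object of class `question_spec`.
#' @export
#' @examples
#' question_spec("wish_die", "wish_to_die_live", 0, 10)
question_spec <- function(question_id, domain, min_raw, max_raw,
                          polarity = c("worse_high", "worse_low")) {
  polarity <- match.arg(polarity)
  domain <- match.arg(domain, ema_domains())
  stopifnot(is.character(question_id), length(question_id) == 1L,
            nzchar(question_id), is.numeric(min_raw), is.numeric(max_raw))
  if (!(max_raw > min_raw)) {
    stop("max_raw must exceed min_raw for question '", question_id, "'")
  }
  structure(list(question_id = question_id, domain = domain,
                 min_raw = as.numeric(min_raw), max_raw = as.numeric(max_raw),
                 polarity = polarity),
            class = "question_spec")
}

#' Recognised symptom domains
#'
#' @return Character vector of the four domain labels.
#' @export
ema_domains <- function() {
  c("wish_to_die_live", "sleep", "negative_feelings", "appetite")
}

#' Assemble a questionnaire schema
#'
#' @param items List of [question_spec()] objects; item order defines the
#'   column order of every downstream observation matrix.
#' @param n_items Required number of items (default 32).
#' @return An object of class `ema_schema`: a list of `question_spec`s with
#'   a `question_id` index.
#' @export
ema_schema <- function(items, n_items = 32L) {
  stopifnot(is.list(items), all(vapply(items, inherits, TRUE, "question_spec")))
  if (length(items) != n_items) {
    stop("schema must contain exactly ", n_items, " items, got ", length(items))
  }
  ids <- vapply(items, `[[`, "", "question_id")
  if (anyDuplicated(ids)) stop("duplicate question_id in schema")
  structure(list(items = items, question_ids = ids), class = "ema_schema")
}

#' @export
print.ema_schema <- function(x, ...) {
  doms <- table(factor(vapply(x$items, `[[`, "", "domain"), levels = ema_domains()))
  cat("EMA questionnaire schema:", length(x$items), "items\n")
  for (d in names(doms)) cat("  ", d, ": ", doms[[d]], " items\n", sep = "")
  invisible(x)
}

#' @export
length.ema_schema <- function(x) length(x$items)

#' Default 32-item risk questionnaire schema
#'
#' The shipped instrument: 32 items over four domains with the standard
#' cardinalities — wish to die / wish to live (2), sleep (10), negative
#' feelings (13) and appetite (7). All items use a 0-10 raw scale. The
#' "wish to live" item and the positively-phrased sleep-quality and
#' appetite-level items are `worse_low`; everything else is `worse_high`.
#' Item wording is not part of the schema; identifiers are positional within
#' each domain.
#'
#' @return An `ema_schema` with 32 items.
#' @export
#' @examples
#' default_schema()
default_schema <- function() {
  mk <- function(id, domain, polarity = "worse_high") {
    question_spec(id, domain, 0, 10, polarity)
  }
  items <- c(
    list(mk("wish_die", "wish_to_die_live"),
         mk("wish_live", "wish_to_die_live", polarity = "worse_low"),
         mk("sleep_quality", "sleep", polarity = "worse_low")),
    lapply(sprintf("sleep_%02d", 2:10), mk, domain = "sleep"),
    lapply(sprintf("negfeel_%02d", 1:13), mk, domain = "negative_feelings"),
    list(mk("appetite_level", "appetite", polarity = "worse_low")),
    lapply(sprintf("appetite_%02d", 2:7), mk, domain = "appetite")
  )
  ema_schema(items)
}

#' Look up items by domain
#'
#' @param schema An `ema_schema`.
#' @param domain A domain label (see [ema_domains()]).
#' @return Integer column indices of the items in that domain.
#' @export
domain_items <- function(schema, domain) {
  domain <- match.arg(domain, ema_domains())
  which(vapply(schema$items, `[[`, "", "domain") == domain)
}

#' Standardise a raw response to the unit interval
#'
#' Maps a raw answer onto \[0, 1\] linearly over the item's range so that the
#' highest standardised value always expresses the worse state: for
#' `worse_high` items the map is `(raw - min) / (max - min)`; for `worse_low`
#' items it is flipped, `1 - (raw - min) / (max - min)`.
#'
#' @param raw Numeric vector of raw responses.
#' @param spec A [question_spec()].
#' @return Numeric vector of scores in \[0, 1\].
#' @export
#' @examples
#' sp <- question_spec("wish_live", "wish_to_die_live", 0, 10, "worse_low")
#' standardize_response(10, sp)  # best state maps to 0
standardize_response <- function(raw, spec) {
  stopifnot(inherits(spec, "question_spec"))
  bad <- !is.na(raw) & (raw < spec$min_raw | raw > spec$max_raw)
  if (any(bad)) {
    stop("raw value out of range [", spec$min_raw, ", ", spec$max_raw,
         "] for question '", spec$question_id, "'")
  }
  s <- (raw - spec$min_raw) / (spec$max_raw - spec$min_raw)
  if (spec$polarity == "worse_low") s <- 1 - s
  s
}

#' Invert standardisation back to the raw scale
#'
#' @param score Numeric vector of unit-interval scores.
#' @param spec A [question_spec()].
#' @return Raw-scale values; exact inverse of [standardize_response()].
#' @export
unstandardize_response <- function(score, spec) {
  stopifnot(inherits(spec, "question_spec"))
  if (any(score < 0 | score > 1, na.rm = TRUE)) {
    stop("score outside [0, 1] for question '", spec$question_id, "'")
  }
  s <- if (spec$polarity == "worse_low") 1 - score else score
  spec$min_raw + s * (spec$max_raw - spec$min_raw)
}

#' Binarize a standardised score
#'
#' A score "scores positive" when it reaches the threshold (inclusive).
#' The default threshold is the midpoint of the worse-is-higher unit scale.
#'
#' @param score Numeric vector (or matrix) of standardised scores in \[0, 1\].
#' @param threshold Scalar in \[0, 1\]; default 0.5.
#' @return Logical vector/matrix: `TRUE` where `score >= threshold`.
#' @export
binarize <- function(score, threshold = 0.5) {
  stopifnot(length(threshold) == 1L, threshold >= 0, threshold <= 1)
  score >= threshold
}

#' Study period schedule
#'
#' Inclusive calendar windows assigning each session date to a period.
#' Defaults follow the study calendar: pre-lockdown 2019-10-01 to 2020-03-13
#' and lockdown 2020-03-14 to 2020-04-14. Dates outside every window are
#' excluded from analysis.
#'
#' @param pre_start,pre_end,lockdown_start,lockdown_end `Date`s or
#'   ISO-8601 strings; both endpoints inclusive.
#' @return An object of class `period_schedule`.
#' @export
period_schedule <- function(pre_start = "2019-10-01", pre_end = "2020-03-13",
                            lockdown_start = "2020-03-14",
                            lockdown_end = "2020-04-14") {
  ps <- lapply(list(pre_start = pre_start, pre_end = pre_end,
                    lockdown_start = lockdown_start,
                    lockdown_end = lockdown_end), as.Date)
  stopifnot(ps$pre_start <= ps$pre_end, ps$lockdown_start <= ps$lockdown_end,
            ps$pre_end < ps$lockdown_start)
  structure(ps, class = "period_schedule")
}

#' Assign dates to study periods
#'
#' @param dates `Date` vector (or coercible).
#' @param schedule A [period_schedule()].
#' @return Character vector with entries `"pre_lockdown"`, `"lockdown"` or
#'   `NA` for dates outside both windows.
#' @export
period_of_date <- function(dates, schedule = period_schedule()) {
  stopifnot(inherits(schedule, "period_schedule"))
  dates <- as.Date(dates)
  out <- rep(NA_character_, length(dates))
  out[dates >= schedule$pre_start & dates <= schedule$pre_end] <- "pre_lockdown"
  out[dates >= schedule$lockdown_start & dates <= schedule$lockdown_end] <- "lockdown"
  out
}

#' Write a schema (plus optional period schedule) to a YAML config
#'
#' @param schema An `ema_schema`.
#' @param path Output file path.
#' @param schedule Optional [period_schedule()] stored alongside the items.
#' @return `path`, invisibly.
#' @export
write_schema_config <- function(schema, path, schedule = NULL) {
  stopifnot(inherits(schema, "ema_schema"))
  cfg <- list(items = lapply(schema$items, unclass))
  if (!is.null(cfg$items[[1]]$question_id)) names(cfg$items) <- NULL
  if (!is.null(schedule)) {
    cfg$periods <- lapply(unclass(schedule), format, "%Y-%m-%d")
  }
  yaml::write_yaml(cfg, path)
  invisible(path)
}

#' Read a schema config written by [write_schema_config()]
#'
#' @param path YAML config path.
#' @return A list with elements `schema` (`ema_schema`) and `schedule`
#'   (`period_schedule` or `NULL`).
#' @export
read_schema_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$items)) stop("config has no 'items' section: ", path)
  items <- lapply(cfg$items, function(it) {
    question_spec(it$question_id, it$domain, it$min_raw, it$max_raw, it$polarity)
  })
  schedule <- NULL
  if (!is.null(cfg$periods)) {
    schedule <- do.call(period_schedule, cfg$periods)
  }
  list(schema = ema_schema(items, n_items = length(items)), schedule = schedule)
}
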