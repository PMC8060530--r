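#' Read a long-format EMA response table
#'
#' Expects delimited text with a header row and columns
#' `patient_id, timestamp, question_id, raw_value` (extra columns are
#' ignored). Every row is validated against the schema: unknown question ids,
#' unparseable timestamps and out-of-range raw values are reported with their
#' line numbers.
#'
#' @param path File path of a CSV/TSV table (delimiter auto-detected from the
#'   header line, or set `sep`).
#' @param schema An `ema_schema` used for validation.
#' @param sep Field delimiter; default `","`.
#' @return A data frame of validated records with columns `patient_id`
#'   (character), `timestamp` (`POSIXct`, minute resolution), `question_id`
#'   (character) and `raw_value` (numeric). Zero-row input yields a zero-row
#'   frame with the same columns.
#' @export
read_ema_table <- function(path, schema, sep = ",") {
  stopifnot(inherits(schema, "ema_schema"))
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          colClasses = "character", stringsAsFactors = FALSE,
                          check.names = TRUE)
  needed <- c("patient_id", "timestamp", "question_id", "raw_value")
  missing <- setdiff(needed, names(df))
  if (length(missing)) {
    stop("EMA table is missing column(s): ", paste(missing, collapse = ", "))
  }
  df <- df[needed]
  if (nrow(df) == 0L) {
    return(data.frame(patient_id = character(), timestamp = as.POSIXct(character()),
                      question_id = character(), raw_value = numeric()))
  }
  line <- seq_len(nrow(df)) + 1L  # +1 for the header line

  unknown <- !(df$question_id %in% schema$question_ids)
  if (any(unknown)) {
    stop("unknown question_id '", df$question_id[which(unknown)[1]],
         "' at line ", line[which(unknown)[1]])
  }
  ts <- as.POSIXct(df$timestamp, tz = "UTC",
                   tryFormats = c("%Y-%m-%dT%H:%M:%OS", "%Y-%m-%dT%H:%M",
                                  "%Y-%m-%d %H:%M:%OS", "%Y-%m-%d %H:%M",
                                  "%Y-%m-%d"),
                   optional = TRUE)
  if (anyNA(ts)) {
    stop("unparseable timestamp '", df$timestamp[which(is.na(ts))[1]],
         "' at line ", line[which(is.na(ts))[1]])
  }
  raw <- suppressWarnings(as.numeric(df$raw_value))
  if (anyNA(raw)) {
    stop("non-numeric raw_value at line ", line[which(is.na(raw))[1]])
  }
  spec_by_id <- stats::setNames(schema$items, schema$question_ids)
  lo <- vapply(spec_by_id[df$question_id], `[[`, 0, "min_raw")
  hi <- vapply(spec_by_id[df$question_id], `[[`, 0, "max_raw")
  bad <- raw < lo | raw > hi
  if (any(bad)) {
    i <- which(bad)[1]
    stop("raw_value ", raw[i], " out of range for question '",
         df$question_id[i], "' at line ", line[i])
  }
  data.frame(patient_id = df$patient_id, timestamp = ts,
             question_id = df$question_id, raw_value = raw)
}

#' Write EMA records to delimited text
#'
#' Raw values are written with 4 decimal places so a write/read round trip
#' reproduces records exactly at that precision; timestamps are ISO-8601.
#'
#' @param records Data frame as returned by [read_ema_table()] or
#'   [simulate_ema_stream()].
#' @param path Output path.
#' @param sep Field delimiter; default `","`.
#' @param digits Decimal places for `raw_value`; default 4.
#' @return `path`, invisibly.
#' @export
write_ema_table <- function(records, path, sep = ",", digits = 4L) {
  out <- data.frame(
    patient_id = as.character(records$patient_id),
    timestamp = format(records$timestamp, "%Y-%m-%dT%H:%M:%S", tz = "UTC"),
    question_id = as.character(records$question_id),
    raw_value = formatC(records$raw_value, format = "f", digits = digits)
  )
  utils::write.table(out, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Assemble an observation matrix from EMA records
#'
#' Sessionises validated records (default: one observation vector per patient
#' per calendar day), standardises each answer with the schema, and returns an
#' N x 32 matrix of unit-interval scores together with an observed-entry mask.
#' The turn-over design answers only a few items per session, so rows carry
#' masks rather than being dropped or imputed. Each row is labelled with its
#' study period; sessions dated outside both windows are excluded and counted
#' in the `n_excluded` attribute. When the same question is answered more than
#' once in a session the last answer (by timestamp) wins; the number of such
#' superseded answers is reported in the `n_superseded` attribute.
#'
#' @param records Validated records (see [read_ema_table()]).
#' @param schema An `ema_schema`; schema order defines column order.
#' @param schedule A [period_schedule()].
#' @param sessionization `"day"` (default, patient x calendar day) or
#'   `"prompt"` (patient x timestamp).
#' @return An object of class `observation_matrix`: a list with `values`
#'   (N x D numeric, `NA` where unobserved), `mask` (N x D logical) and
#'   `row_meta` (data frame: `patient_id`, `date`, `period`).
#' @export
build_observation_matrix <- function(records, schema,
                                     schedule = period_schedule(),
                                     sessionization = c("day", "prompt")) {
  stopifnot(inherits(schema, "ema_schema"))
  sessionization <- match.arg(sessionization)
  if (nrow(records) == 0L) stop("no records supplied")

  date <- as.Date(records$timestamp, tz = "UTC")
  period <- period_of_date(date, schedule)
  n_excluded_records <- sum(is.na(period))
  keep <- !is.na(period)
  if (!any(keep)) stop("all records fall outside the period schedule")
  records <- records[keep, , drop = FALSE]
  date <- date[keep]; period <- period[keep]

  session_key <- if (sessionization == "day") {
    paste(records$patient_id, format(date), sep = "\r")
  } else {
    paste(records$patient_id, format(records$timestamp, "%Y-%m-%dT%H:%M:%S"),
          sep = "\r")
  }
  # last answer wins within a session: order by timestamp, later overwrites
  ord <- order(session_key, records$timestamp)
  records <- records[ord, , drop = FALSE]
  session_key <- session_key[ord]; date <- date[ord]; period <- period[ord]
  dup <- duplicated(cbind(session_key, records$question_id), fromLast = TRUE)
  n_superseded <- sum(dup)

  rows <- match(session_key, unique(session_key))
  cols <- match(records$question_id, schema$question_ids)
  n <- max(rows); d <- length(schema)
  values <- matrix(NA_real_, n, d, dimnames = list(NULL, schema$question_ids))
  for (j in seq_len(d)) {
    sel <- which(cols == j)
    if (length(sel)) {
      values[rows[sel], j] <-
        standardize_response(records$raw_value[sel], schema$items[[j]])
    }
  }
  mask <- !is.na(values)
  first <- !duplicated(session_key)
  meta <- data.frame(patient_id = records$patient_id[first],
                     date = date[first], period = period[first])

  nonempty <- rowSums(mask) > 0L
  structure(list(values = values[nonempty, , drop = FALSE],
                 mask = mask[nonempty, , drop = FALSE],
                 row_meta = meta[nonempty, , drop = FALSE]),
            class = "observation_matrix",
            n_excluded = n_excluded_records,
            n_superseded = n_superseded)
}

#' @export
print.observation_matrix <- function(x, ...) {
  tab <- table(x$row_meta$period)
  cat("observation_matrix:", nrow(x$values), "sessions x", ncol(x$values),
      "items;", sum(x$mask), "observed entries\n")
  cat("  periods:", paste(names(tab), tab, sep = " = ", collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.observation_matrix <- function(x) dim(x$values)
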