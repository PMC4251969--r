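#' Epoch-level count series
#'
#' Container for one day of accelerometer impulse counts at a fixed epoch
#' length, with optional ground-truth labels (used for simulated, labeled
#' days where the generating state and range of every count are known).
#'
#' @param counts nonnegative numeric vector, length `T >= 1`.
#' @param epoch_seconds epoch length in seconds.
#' @param day identifier of the day.
#' @param true_state optional integer vector of generating states.
#' @param true_pa_level optional numeric vector of generating PA-levels.
#' @param true_range optional character vector of true activity ranges.
#' @return an object of class `count_series`.
#' @export
count_series <- function(counts, epoch_seconds = 15L, day = 1L,
                         true_state = NULL, true_pa_level = NULL,
                         true_range = NULL) {
  counts <- as.numeric(counts)
  if (!length(counts)) stop("counts must be non-empty", call. = FALSE)
  if (any(!is.finite(counts)) || any(counts < 0))
    stop("counts must be finite and nonnegative", call. = FALSE)
  if (epoch_seconds <= 0) stop("epoch_seconds must be positive", call. = FALSE)
  for (lab in list(true_state, true_pa_level, true_range))
    if (!is.null(lab) && length(lab) != length(counts))
      stop("label columns must match the series length", call. = FALSE)
  structure(list(counts = counts, epoch_seconds = as.integer(epoch_seconds),
                 day = day, true_state = true_state,
                 true_pa_level = true_pa_level,
                 true_range = if (is.null(true_range)) NULL
                              else as.character(true_range)),
            class = "count_series")
}

#' @export
print.count_series <- function(x, ...) {
  cat(sprintf("<count_series day=%s: T=%d epochs x %ds%s>\n", x$day,
              length(x$counts), x$epoch_seconds,
              if (!is.null(x$true_state)) ", labeled" else ""))
  invisible(x)
}

#' @export
length.count_series <- function(x) length(x$counts)

# Accept either a bare numeric vector or a count_series everywhere.
as_counts <- function(x) {
  if (inherits(x, "count_series")) return(x$counts)
  if (!is.numeric(x)) stop("expected a numeric vector or count_series",
                           call. = FALSE)
  as.numeric(x)
}

#' Read count series from a delimited text file
#'
#' Expects a header and at least a `count` column; optional columns
#' `day`, `epoch_index`, `true_state`, `true_pa_level`, `true_range` are
#' used when present (other columns are ignored but preserved by
#' [write_series()] round-trips of objects this function created). A file
#' holding several days (distinguished by the `day` column) yields one
#' `count_series` per day.
#'
#' @param path file path.
#' @param sep field separator.
#' @param epoch_seconds epoch length to record on the series.
#' @return list of [count_series()].
#' @export
read_series <- function(path, sep = ",", epoch_seconds = 15L) {
  df <- read.csv(path, sep = sep, stringsAsFactors = FALSE)
  if (!"count" %in% names(df))
    stop(sprintf("'%s': missing required column 'count'", path), call. = FALSE)
  if (!is.numeric(df$count))
    stop(sprintf("'%s': column 'count' is not numeric", path), call. = FALSE)
  bad <- which(!is.finite(df$count) | df$count < 0)
  if (length(bad))
    stop(sprintf("'%s': invalid count at line %d (data row %d)",
                 path, bad[1L] + 1L, bad[1L]), call. = FALSE)
  if (!"day" %in% names(df)) df$day <- 1L
  lapply(split(df, df$day), function(d)
    count_series(d$count, epoch_seconds = epoch_seconds, day = d$day[1L],
                 true_state = d[["true_state"]],
                 true_pa_level = d[["true_pa_level"]],
                 true_range = d[["true_range"]]))
}

series_to_df <- function(s) {
  df <- data.frame(day = s$day, epoch_index = seq_along(s$counts),
                   count = s$counts)
  if (!is.null(s$true_state)) df$true_state <- s$true_state
  if (!is.null(s$true_pa_level)) df$true_pa_level <- s$true_pa_level
  if (!is.null(s$true_range)) df$true_range <- s$true_range
  df
}

#' Write count series to a delimited text file
#'
#' @param series a [count_series()] or list of them.
#' @param path output file path.
#' @param sep field separator.
#' @return `path`, invisibly.
#' @export
write_series <- function(series, path, sep = ",") {
  if (inherits(series, "count_series")) series <- list(series)
  df <- do.call(rbind, lapply(series, series_to_df))
  write.csv2 <- function(x, f) write.table(x, f, sep = sep, row.names = FALSE,
                                           quote = FALSE)
  write.csv2(df, path)
  invisible(path)
}

#' Write a study summary report to delimited text
#'
#' Lays the summary out one row per measure and method with columns
#' `mean`, `sd`, `min`, `median`, `max`, `pct_correct` (the layout of the
#' method-comparison table).
#'
#' @param summary a `study_summary` from [evaluate_study()].
#' @param path output file path.
#' @param sep field separator.
#' @return `path`, invisibly.
#' @export
write_report <- function(summary, path, sep = ",") {
  stopifnot(inherits(summary, "study_summary"))
  utils::write.table(summary$table, path, sep = sep, row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Read a cutpoint scheme from a key-value config file
#'
#' The file holds `key = value` lines: `name`, `epoch_seconds`,
#' `thresholds` (comma-separated) and `labels` (comma-separated), e.g.
#' \preformatted{name = pate
#' epoch_seconds = 15
#' thresholds = 420, 842
#' labels = LIG, MOD, VIG}
#'
#' @param path file path.
#' @return a [cutpoint_scheme()].
#' @export
read_scheme <- function(path) {
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  kv <- strsplit(lines, "=", fixed = TRUE)
  if (any(lengths(kv) != 2L))
    stop(sprintf("'%s': expected 'key = value' lines", path), call. = FALSE)
  vals <- setNames(trimws(vapply(kv, `[`, "", 2L)),
                   trimws(vapply(kv, `[`, "", 1L)))
  need <- c("thresholds", "labels")
  if (!all(need %in% names(vals)))
    stop(sprintf("'%s': missing key(s) %s", path,
                 paste(setdiff(need, names(vals)), collapse = ", ")),
         call. = FALSE)
  split_csv <- function(s) trimws(strsplit(s, ",", fixed = TRUE)[[1L]])
  get_or <- function(key, default)
    if (key %in% names(vals)) unname(vals[key]) else default
  cutpoint_scheme(thresholds = as.numeric(split_csv(vals["thresholds"])),
                  labels = split_csv(vals["labels"]),
                  epoch_seconds = as.integer(get_or("epoch_seconds", "15")),
                  name = get_or("name", "custom"))
}
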