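#' Cutpoint schemes for activity ranges
#'
#' A cutpoint scheme is an ordered set of thresholds (counts per epoch)
#' separating activity ranges. The default scheme follows Pate et al. for
#' 15-second epochs: epochs with fewer than 420 counts are light activity
#' (LIG), 420-841 counts moderate (MOD) and 842 or more vigorous (VIG).
#' Intervals are half-open, `[t_{i-1}, t_i)`, so integer counts reproduce
#' the published "<420 / 420-841 / >841" rule exactly while real-valued
#' decoded PA-levels remain well defined.
#'
#' @param thresholds strictly increasing positive thresholds
#'   (counts/epoch).
#' @param labels range names, one more than there are thresholds, ordered
#'   from lowest to highest intensity.
#' @param epoch_seconds epoch length the thresholds refer to.
#' @param name scheme name.
#' @return an object of class `cutpoint_scheme`.
#' @examples
#' sch <- pate_scheme()
#' assign_range(c(419, 420, 841, 842), sch)
#' @export
cutpoint_scheme <- function(thresholds, labels, epoch_seconds = 15L,
                            name = "custom") {
  thresholds <- as.numeric(thresholds)
  if (length(labels) != length(thresholds) + 1L)
    stop("need exactly one more label than thresholds", call. = FALSE)
  if (any(thresholds <= 0) || any(diff(thresholds) <= 0))
    stop("thresholds must be positive and strictly increasing", call. = FALSE)
  if (epoch_seconds <= 0) stop("epoch_seconds must be positive", call. = FALSE)
  structure(list(name = name, thresholds = thresholds,
                 labels = as.character(labels),
                 epoch_seconds = as.integer(epoch_seconds)),
            class = "cutpoint_scheme")
}

#' @rdname cutpoint_scheme
#' @export
pate_scheme <- function() {
  cutpoint_scheme(thresholds = c(420, 842), labels = c("LIG", "MOD", "VIG"),
                  epoch_seconds = 15L, name = "pate")
}

#' @export
print.cutpoint_scheme <- function(x, ...) {
  cat(sprintf("<cutpoint_scheme '%s' (%ds epochs): %s>\n", x$name,
              x$epoch_seconds,
              paste(x$labels, collapse = sprintf(" | ")),
              collapse = ""))
  cat("thresholds:", paste(x$thresholds, collapse = ", "), "counts/epoch\n")
  invisible(x)
}

#' Assign counts or PA-levels to activity ranges
#'
#' @param value nonnegative counts or decoded PA-levels (counts/epoch).
#' @param scheme a [cutpoint_scheme()].
#' @return factor of range labels (levels in scheme order), same length as
#'   `value`.
#' @export
assign_range <- function(value, scheme = pate_scheme()) {
  stopifnot(inherits(scheme, "cutpoint_scheme"))
  if (any(!is.finite(value)) || any(value < 0))
    stop("values must be finite and nonnegative", call. = FALSE)
  idx <- findInterval(value, scheme$thresholds) + 1L
  factor(scheme$labels[idx], levels = scheme$labels)
}

#' Extract bouts from a range-label sequence
#'
#' A bout is a maximal run of consecutive epochs in the same activity
#' range; the bout count of a day is therefore one more than the number of
#' label changes.
#'
#' @param ranges character or factor sequence of range labels, length `>= 1`.
#' @return an object of class `bout_list`: data frame with columns `range`,
#'   `start` (first epoch index) and `length` (epochs).
#' @export
extract_bouts <- function(ranges) {
  if (!length(ranges)) stop("range sequence must be non-empty", call. = FALSE)
  r <- rle(as.character(ranges))
  structure(data.frame(range = r$values,
                       start = cumsum(c(1L, head(r$lengths, -1L))),
                       length = r$lengths,
                       stringsAsFactors = FALSE),
            class = c("bout_list", "data.frame"))
}

#' Expand a bout list back into a per-epoch label sequence
#'
#' Inverse of [extract_bouts()].
#'
#' @param bouts a `bout_list`.
#' @return character vector of range labels.
#' @export
bouts_to_ranges <- function(bouts) {
  stopifnot(inherits(bouts, "bout_list"))
  rep(bouts$range, bouts$length)
}

#' Number of bouts in a range sequence
#'
#' @param ranges range-label sequence.
#' @return integer bout count.
#' @export
count_bouts <- function(ranges) {
  nrow(extract_bouts(ranges))
}
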