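#' Classify a day of counts with the traditional cutpoint method
#'
#' Assigns every epoch's raw count directly to an activity range via the
#' cutpoint scheme and extracts bouts from the resulting range sequence.
#'
#' @param x numeric count vector or [count_series()].
#' @param scheme a [cutpoint_scheme()].
#' @return an object of class `classification_result` with per-epoch
#'   `ranges`, the `bouts` table, `bout_count`, and `method = "cutpoint"`
#'   (`states`, `pa_levels`, `n_activities` and `fit` are `NULL`/`NA`: the
#'   cutpoint method cannot identify activities).
#' @export
classify_traditional <- function(x, scheme = pate_scheme()) {
  day <- if (inherits(x, "count_series")) x$day else NA
  counts <- as_counts(x)
  ranges <- assign_range(counts, scheme)
  bouts <- extract_bouts(ranges)
  classification_result("cutpoint", day, ranges, bouts,
                        states = NULL, pa_levels = NULL,
                        n_activities = NA_integer_, fit = NULL)
}

#' Classify a day of counts with the HMM-extended cutpoint method
#'
#' The three-step procedure: (1) train HMMs with the requested emission
#' family over the candidate numbers of states and select one by AIC/BIC;
#' (2) decode the most likely activity sequence (globally by Viterbi, or
#' locally from smoothed posteriors) and replace each count by the decoded
#' state's PA-level; (3) assign each decoded PA-level to an activity range
#' via the cutpoints. Because whole stretches of epochs share one decoded
#' PA-level, the range sequence is far less fragmented than under the
#' traditional method.
#'
#' @inheritParams classify_traditional
#' @param family emission family: `"gauss"`, `"pois"` or `"genpois"`.
#' @param m_range candidate numbers of states.
#' @param decoding `"global"` (Viterbi) or `"local"` (posterior argmax).
#' @param criterion model-selection criterion, see [select_model()].
#' @param restarts EM restarts per candidate model.
#' @param seed optional integer seed for the restart jitter.
#' @param ... passed to [select_model()] (e.g. `tol`, `max_iter`).
#' @return a `classification_result`; `n_activities` is the selected number
#'   of states. If no candidate model converges the result has
#'   `converged = FALSE` and carries the failure reason (the day is
#'   reported, not dropped).
#' @export
classify_hmm <- function(x, family = c("gauss", "pois", "genpois"),
                         scheme = pate_scheme(), m_range = 2:6,
                         decoding = c("global", "local"),
                         criterion = "parsimony", restarts = 3L, seed = NULL,
                         ...) {
  family <- match.arg(family)
  decoding <- match.arg(decoding)
  day <- if (inherits(x, "count_series")) x$day else NA
  counts <- as_counts(x)
  fit <- tryCatch(
    select_model(counts, family = family, m_range = m_range,
                 criterion = criterion, restarts = restarts, seed = seed,
                 ...),
    error = function(e) e)
  if (inherits(fit, "error")) {
    out <- classification_result(paste0("hmm-", family), day,
                                 ranges = NULL, bouts = NULL,
                                 states = NULL, pa_levels = NULL,
                                 n_activities = NA_integer_, fit = NULL)
    out$converged <- FALSE
    out$failure_reason <- conditionMessage(fit)
    return(out)
  }
  dec <- if (decoding == "global") viterbi(fit$model, counts)
         else local_decode(fit$model, counts)
  ranges <- assign_range(dec$pa_levels, scheme)
  classification_result(paste0("hmm-", family), day, ranges,
                        extract_bouts(ranges), states = dec$states,
                        pa_levels = dec$pa_levels,
                        n_activities = fit$model$m, fit = fit)
}

classification_result <- function(method, day, ranges, bouts, states,
                                  pa_levels, n_activities, fit) {
  structure(list(method = method, day = day, ranges = ranges, bouts = bouts,
                 bout_count = if (is.null(bouts)) NA_integer_
                              else nrow(bouts),
                 states = states, pa_levels = pa_levels,
                 n_activities = n_activities, fit = fit,
                 converged = TRUE, failure_reason = NULL),
            class = "classification_result")
}

#' @export
print.classification_result <- function(x, ...) {
  if (!x$converged) {
    cat(sprintf("<classification [%s] day %s: FAILED (%s)>\n", x$method,
                x$day, x$failure_reason))
    return(invisible(x))
  }
  cat(sprintf("<classification [%s] day %s: %d epochs, %d bouts%s>\n",
              x$method, x$day, length(x$ranges), x$bout_count,
              if (is.na(x$n_activities)) ""
              else sprintf(", %d activities", x$n_activities)))
  invisible(x)
}

#' Misclassification rate between true and estimated range sequences
#'
#' @param true_ranges true per-epoch activity ranges.
#' @param est_ranges estimated per-epoch activity ranges, same length.
#' @return percent of epochs assigned to a range other than the true one,
#'   in `[0, 100]`.
#' @export
misclassification_rate <- function(true_ranges, est_ranges) {
  if (length(true_ranges) != length(est_ranges))
    stop("range sequences must have equal length", call. = FALSE)
  100 * mean(as.character(true_ranges) != as.character(est_ranges))
}

#' Compare classification methods on labeled days
#'
#' Runs every requested method on every labeled day and summarizes, per
#' method, the distribution of per-day misclassification rates, identified
#' bout counts and identified activity counts, together with the percent of
#' days on which the bout count (respectively activity count) exactly
#' equals the truth. Days on which a method fails to converge are excluded
#' from that method's statistics and reported through its failure rate.
#'
#' @param days list of `labeled_day` objects (see [generate_day()]), or a
#'   `sim_study`.
#' @param methods character vector among `"cutpoint"`, `"hmm-gauss"`,
#'   `"hmm-pois"`, `"hmm-genpois"`; alternatively a named list whose
#'   elements are either such names or custom classifier functions
#'   `function(day, scheme)` returning a `classification_result`.
#' @param scheme a [cutpoint_scheme()].
#' @param m_range,criterion,decoding,restarts passed to [classify_hmm()].
#' @param seed master seed; per-day fitting seeds are derived from it.
#' @param verbose print one line per day and method.
#' @return an object of class `study_summary`: `table` (measure x method
#'   summary: mean, sd, min, median, max, pct_correct), `per_day` (long
#'   data frame of per-day results) and `failure_rate` (per method, in %).
#' @export
evaluate_study <- function(days,
                           methods = c("cutpoint", "hmm-gauss"),
                           scheme = pate_scheme(), m_range = 2:6,
                           criterion = "parsimony",
                           decoding = "global", restarts = 3L, seed = 1L,
                           verbose = FALSE) {
  if (inherits(days, "sim_study")) days <- days$days
  stopifnot(length(days) >= 1L)
  if (is.character(methods)) methods <- setNames(as.list(methods), methods)
  if (!is.list(methods) || is.null(names(methods)) ||
      any(!nzchar(names(methods))))
    stop("methods must be a character vector or a named list", call. = FALSE)
  known <- c("cutpoint", "hmm-gauss", "hmm-pois", "hmm-genpois")
  fit_seeds <- day_seeds(seed, length(days))
  rows <- list()
  for (mn in names(methods)) {
    meth <- methods[[mn]]
    if (is.character(meth) && !meth %in% known)
      stop(sprintf("unknown method '%s'", meth), call. = FALSE)
    for (di in seq_along(days)) {
      d <- days[[di]]
      res <- if (is.function(meth)) {
        meth(d, scheme)
      } else if (meth == "cutpoint") {
        classify_traditional(d, scheme)
      } else {
        classify_hmm(d, family = sub("^hmm-", "", meth), scheme = scheme,
                     m_range = m_range, decoding = decoding,
                     criterion = criterion, restarts = restarts,
                     seed = fit_seeds[di])
      }
      ok <- isTRUE(res$converged)
      rows[[length(rows) + 1L]] <- data.frame(
        method = mn, day = di, converged = ok,
        mcr = if (ok) misclassification_rate(d$true_range, res$ranges)
              else NA_real_,
        bouts = if (ok) res$bout_count else NA_integer_,
        true_bouts = d$true_bout_count,
        activities = res$n_activities,
        true_activities = d$true_activity_count)
      if (verbose)
        message(sprintf("day %d [%s]: %s", di, mn,
                        if (ok) sprintf("MCR %.2f%%, %d bouts",
                                        rows[[length(rows)]]$mcr,
                                        rows[[length(rows)]]$bouts)
                        else "not converged"))
    }
  }
  per_day <- do.call(rbind, rows)
  stat_row <- function(measure, mn, v, correct) {
    v <- v[is.finite(v)]
    data.frame(measure = measure, method = mn,
               mean = if (length(v)) mean(v) else NA_real_,
               sd = if (length(v) > 1L) sd(v) else NA_real_,
               min = if (length(v)) min(v) else NA_real_,
               median = if (length(v)) median(v) else NA_real_,
               max = if (length(v)) max(v) else NA_real_,
               pct_correct = correct)
  }
  tabs <- list()
  failure_rate <- numeric(0)
  for (mn in names(methods)) {
    p <- per_day[per_day$method == mn, ]
    okp <- p[p$converged, ]
    failure_rate[mn] <- 100 * mean(!p$converged)
    tabs[[length(tabs) + 1L]] <-
      stat_row("mcr", mn, okp$mcr, 100 - mean(okp$mcr))
    tabs[[length(tabs) + 1L]] <-
      stat_row("bouts", mn, okp$bouts,
               100 * mean(okp$bouts == okp$true_bouts))
    act_correct <- if (all(is.na(okp$activities))) NA_real_
                   else 100 * mean(okp$activities == okp$true_activities,
                                   na.rm = TRUE)
    tabs[[length(tabs) + 1L]] <-
      stat_row("activities", mn, okp$activities, act_correct)
  }
  structure(list(table = do.call(rbind, tabs), per_day = per_day,
                 failure_rate = failure_rate),
            class = "study_summary")
}

#' @export
print.study_summary <- function(x, digits = 2, ...) {
  cat(sprintf("<study_summary: %d days, methods: %s>\n",
              length(unique(x$per_day$day)),
              paste(names(x$failure_rate), collapse = ", ")))
  print(x$table, row.names = FALSE, digits = digits + 2)
  if (any(x$failure_rate > 0)) {
    cat("convergence failures [%]:\n")
    print(round(x$failure_rate, digits))
  }
  invisible(x)
}
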