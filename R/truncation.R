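#' Limited-probing (truncation) experiment for one example
#'
#' Compares exhaustive listing with interviews limited to at most \code{k}
#' responses per person: unique-item yields at small sample sizes, the
#' saturation point of the truncated series, and the capture of the
#' full-listing salient-item reference set. All subsamples are prefixes in
#' stored respondent order ("the first n interviews"). The information
#' heuristic \code{info_bits} is mean list length times sample size —
#' roughly how many response tokens a design collects.
#'
#' The salient reference set is always derived from full lists (prevalence
#' >= \code{salience_threshold} among the first \code{reference_n}
#' respondents), and held fixed when evaluating truncated capture.
#'
#' @param data a \code{\link{freelist}} object.
#' @param k truncation depth (default 3, emulating a typical open-ended
#'   question without probing).
#' @param salience_threshold,reference_n parameters of the salient set.
#' @param yield_n sample sizes at which unique-item yields are compared.
#' @return list with elements \code{example}, \code{k}, \code{N},
#'   \code{mean_L}, \code{unique_full}, \code{unique_at_n} (data frame of
#'   full vs truncated yields by n), \code{n_sat_full},
#'   \code{n_sat_truncated}, \code{capture} (data frame of salient-capture
#'   proportions), \code{info_bits}. Capture fields are NA when
#'   N < \code{reference_n}.
#' @export
truncation_experiment <- function(data, k = 3, salience_threshold = 0.20,
                                  reference_n = 20, yield_n = c(10, 20)) {
  stopifnot(inherits(data, "freelist"))
  N <- n_respondents(data)
  trunc <- truncate_lists(data, k)
  yield_n <- yield_n[yield_n <= N]

  uniq_at <- function(fl, n) length(item_universe(head_respondents(fl, n)))
  yields <- data.frame(
    n = yield_n,
    full = vapply(yield_n, function(n) uniq_at(data, n), integer(1)),
    truncated = vapply(yield_n, function(n) uniq_at(trunc, n), integer(1))
  )

  n_sat_of <- function(fl) {
    fit <- tryCatch(select_best_fit(fit_accumulation_models(
      new_item_series(fl))), error = function(e) NULL)
    if (is.null(fit)) return(NA_integer_)
    saturation_point(fit, 1)$n_sat
  }

  capture <- NULL
  if (N >= reference_n) {
    sal <- salient_set(data, threshold = salience_threshold,
                       reference_n = reference_n)
    grid <- data.frame(
      n = c(10L, 20L, 15L, 10L),
      k = c(NA_integer_, k, k, k),
      stringsAsFactors = FALSE
    )
    grid <- grid[grid$n <= N, , drop = FALSE]
    grid$capture <- mapply(function(n, kk)
      capture_proportion(sal, data, n, k = if (is.na(kk)) NULL else kk),
      grid$n, grid$k)
    grid$condition <- ifelse(is.na(grid$k), "full", paste0("k", grid$k))
    capture <- list(salient_items = sal, table = grid)
  }

  list(
    example = data$domain, k = k, N = N,
    mean_L = mean(list_lengths(data)),
    unique_full = length(item_universe(data)),
    unique_at_n = yields,
    n_sat_full = n_sat_of(data),
    n_sat_truncated = n_sat_of(trunc),
    capture = capture,
    info_bits = data.frame(
      n = yield_n,
      full = mean(list_lengths(data)) * yield_n,
      truncated = mean(list_lengths(trunc)) * yield_n)
  )
}

#' Truncation experiment across a corpus of examples
#'
#' Runs \code{\link{truncation_experiment}} on every example and aggregates:
#' the median (and range) of truncated saturation sample sizes, the
#' unweighted mean salient-capture proportion at each condition, and the
#' number of examples capturing more than 95\% of salient items in the
#' first 10 full-listing interviews.
#'
#' @param datasets named list of \code{\link{freelist}} objects.
#' @param k truncation depth.
#' @param ... passed to \code{\link{truncation_experiment}}.
#' @return list with \code{reports} (per-example), \code{table} (one row
#'   per example), and \code{summary}.
#' @export
batch_truncation <- function(datasets, k = 3, ...) {
  stopifnot(length(datasets) >= 1L)
  reports <- lapply(datasets, truncation_experiment, k = k, ...)
  cap_at <- function(rep, n, cond) {
    if (is.null(rep$capture)) return(NA_real_)
    tb <- rep$capture$table
    v <- tb$capture[tb$n == n & tb$condition == cond]
    if (length(v)) v[1] else NA_real_
  }
  tab <- do.call(rbind, lapply(names(reports), function(nm) {
    r <- reports[[nm]]
    data.frame(
      example = nm, N = r$N, mean_L = round(r$mean_L, 1),
      unique_items = r$unique_full,
      n_sat_full = r$n_sat_full, n_sat_truncated = r$n_sat_truncated,
      capture_full_n10 = cap_at(r, 10, "full"),
      capture_trunc_n20 = cap_at(r, 20, paste0("k", k)),
      capture_trunc_n15 = cap_at(r, 15, paste0("k", k)),
      capture_trunc_n10 = cap_at(r, 10, paste0("k", k)),
      stringsAsFactors = FALSE
    )
  }))
  v <- tab$n_sat_truncated[!is.na(tab$n_sat_truncated)]
  summary <- list(
    median_n_sat_truncated = stats::median(v),
    range_n_sat_truncated = if (length(v)) range(v) else c(NA, NA),
    mean_capture_full_n10 = mean(tab$capture_full_n10, na.rm = TRUE),
    mean_capture_trunc_n20 = mean(tab$capture_trunc_n20, na.rm = TRUE),
    mean_capture_trunc_n15 = mean(tab$capture_trunc_n15, na.rm = TRUE),
    mean_capture_trunc_n10 = mean(tab$capture_trunc_n10, na.rm = TRUE),
    n_over_95_full_n10 = sum(tab$capture_full_n10 > 0.95, na.rm = TRUE)
  )
  list(reports = reports, table = tab, summary = summary)
}
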