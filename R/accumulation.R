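#' New-item series
#'
#' For respondents taken in their stored order, counts the items each
#' respondent is the first to mention. The first respondent contributes
#' their whole list; later respondents repeat some items and add fewer and
#' fewer new ones — the descending curve that saturation modelling fits.
#'
#' Respondents are never reordered: reordering to best fit a saturation
#' curve makes saturation appear earlier than it is. A permutation-averaged
#' diagnostic is available via \code{\link{permuted_new_item_series}}.
#'
#' @param data a \code{\link{freelist}} object.
#' @return data frame with columns \code{n} (respondent position 1..N),
#'   \code{new_items} (count first observed at that position), and
#'   \code{cumulative_unique}. The \code{new_items} column sums to the size
#'   of the item universe.
#' @examples
#' fl <- freelist(list(c("a", "b", "c"), c("b", "d")))
#' new_item_series(fl)
#' @export
new_item_series <- function(data) {
  stopifnot(inherits(data, "freelist"))
  long <- as.data.frame(data)
  # position index of the respondent who first mentions each distinct item
  pos <- match(long$respondent[!duplicated(long$response)],
               names(data$respondents))
  y <- tabulate(pos, nbins = n_respondents(data))
  data.frame(n = seq_along(y), new_items = y, cumulative_unique = cumsum(y))
}

#' Cumulative accumulation curve
#'
#' @param series a new-item series from \code{\link{new_item_series}}.
#' @return integer vector of cumulative unique-item counts by sample size.
#' @export
accumulation_curve <- function(series) {
  stopifnot(is.data.frame(series), "new_items" %in% names(series))
  cumsum(series$new_items)
}

#' Permutation-averaged new-item series (diagnostic)
#'
#' Averages the new-item series over random respondent orderings. This
#' smooths the curve but hides order effects, so it is a diagnostic only —
#' never an input to saturation fitting, which uses the stored order.
#'
#' @param data a \code{\link{freelist}} object.
#' @param permutations number of random orderings.
#' @return data frame with columns \code{n} and \code{mean_new_items}.
#' @export
permuted_new_item_series <- function(data, permutations = 100) {
  stopifnot(inherits(data, "freelist"))
  N <- n_respondents(data)
  acc <- matrix(0, nrow = permutations, ncol = N)
  for (b in seq_len(permutations)) {
    perm <- freelist(data$respondents[sample.int(N)], domain = data$domain,
                     normalize = FALSE)
    acc[b, ] <- new_item_series(perm)$new_items
  }
  data.frame(n = seq_len(N), mean_new_items = colMeans(acc))
}
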