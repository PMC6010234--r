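#' Construct a free-list dataset
#'
#' A free list is one ordered list of responses per respondent for a single
#' topical domain ("name all the X you can think of"). The constructor
#' normalises labels (case fold, whitespace collapse, optional synonym map)
#' and drops within-list duplicates, keeping the earliest mention so that
#' rank semantics are preserved for the salience indices.
#'
#' @param respondents a named list; each element is a character vector of
#'   responses in order of mention. Names are respondent ids; unnamed lists
#'   get ids \code{"r1"}, \code{"r2"}, ... Respondent order is meaningful:
#'   every downstream analysis uses the stored order.
#' @param domain a single label for the topical domain.
#' @param synonyms optional named character vector mapping raw variant
#'   labels to canonical labels (applied after normalisation).
#' @param normalize if \code{FALSE}, labels are taken as already canonical
#'   (duplicates within a list are still dropped).
#' @return an object of class \code{"freelist"}: a list with elements
#'   \code{domain} (label) and \code{respondents} (named list of ordered,
#'   normalised item vectors).
#' @examples
#' fl <- freelist(list(a = c("Apple", "pear "), b = "apple"), domain = "fruits")
#' item_universe(fl)
#' @export
freelist <- function(respondents, domain = "domain", synonyms = NULL,
                     normalize = TRUE) {
  if (!is.list(respondents) || length(respondents) < 1L)
    stop("'respondents' must be a non-empty list of character vectors")
  ids <- names(respondents)
  if (is.null(ids) || any(!nzchar(ids)))
    ids <- paste0("r", seq_along(respondents))
  if (anyDuplicated(ids))
    stop("duplicate respondent ids")
  lists <- lapply(respondents, function(x) {
    x <- as.character(x)
    if (length(x) && normalize) x <- normalize_label(x, synonyms = synonyms)
    x[!duplicated(x)]
  })
  names(lists) <- ids
  structure(list(domain = domain, respondents = lists), class = "freelist")
}

#' @export
print.freelist <- function(x, ...) {
  L <- list_lengths(x)
  cat(sprintf("Free-list dataset '%s': %d respondents, %d unique items\n",
              x$domain, n_respondents(x), length(item_universe(x))))
  cat(sprintf("  list lengths: mean %.1f (range %d-%d)\n",
              mean(L), min(L), max(L)))
  invisible(x)
}

#' Number of respondents in a free-list dataset
#' @param data a \code{freelist} object.
#' @return integer sample size N.
#' @export
n_respondents <- function(data) {
  stopifnot(inherits(data, "freelist"))
  length(data$respondents)
}

#' List lengths per respondent
#' @param data a \code{freelist} object.
#' @return named integer vector of per-respondent list lengths (after
#'   normalisation and de-duplication).
#' @export
list_lengths <- function(data) {
  stopifnot(inherits(data, "freelist"))
  vapply(data$respondents, length, integer(1))
}

#' Observed item universe
#' @param data a \code{freelist} object.
#' @return character vector of all distinct normalised items, in first
#'   overall appearance order.
#' @export
item_universe <- function(data) {
  stopifnot(inherits(data, "freelist"))
  items <- unlist(data$respondents, use.names = FALSE)
  items[!duplicated(items)]
}

#' Convert a free-list dataset to a long data frame
#' @param x a \code{freelist} object.
#' @param ... unused.
#' @return data frame with columns \code{respondent}, \code{order} (1-based
#'   rank of mention), \code{response}.
#' @export
as.data.frame.freelist <- function(x, ...) {
  L <- list_lengths(x)
  data.frame(
    respondent = rep(names(x$respondents), L),
    order = unlist(lapply(L, seq_len), use.names = FALSE),
    response = unlist(x$respondents, use.names = FALSE),
    stringsAsFactors = FALSE, row.names = NULL
  )
}

#' Keep only the first n respondents
#'
#' Prefix subsampling in stored respondent order; used for the "first n
#' interviews" comparisons. No resampling or reordering is done.
#'
#' @param data a \code{freelist} object.
#' @param n number of respondents to keep (must not exceed N).
#' @return a \code{freelist} with the first \code{n} respondents.
#' @export
head_respondents <- function(data, n) {
  stopifnot(inherits(data, "freelist"))
  n <- as.integer(n)
  if (n < 1L || n > n_respondents(data))
    stop("'n' must be between 1 and the number of respondents")
  freelist(data$respondents[seq_len(n)], domain = data$domain,
           normalize = FALSE)
}

#' Truncate every list to at most k responses
#'
#' Emulates limited probing / standard open-ended questioning: each
#' respondent keeps only their first \code{k} responses. Respondent order is
#' unchanged and the item universe is recomputed from the truncated lists.
#'
#' @param data a \code{freelist} object.
#' @param k maximum responses per respondent (\code{k >= 1}).
#' @return a \code{freelist} of prefix-truncated lists.
#' @examples
#' fl <- freelist(list(c("a", "b", "c", "d"), c("b", "a")))
#' list_lengths(truncate_lists(fl, 3))
#' @export
truncate_lists <- function(data, k) {
  stopifnot(inherits(data, "freelist"))
  k <- as.integer(k)
  if (is.na(k) || k < 1L) stop("'k' must be a positive integer")
  freelist(lapply(data$respondents, utils::head, n = k),
           domain = data$domain, normalize = FALSE)
}
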