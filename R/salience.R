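#' Per-item salience table
#'
#' Computes, for every item in the observed universe: the number of lists
#' containing it (\code{freq}), its prevalence \code{p = freq / N}, the mean
#' of its within-list ranks (\code{mean_rank}), and the Smith and Sutrop
#' salience indices. Prevalence measures how widely an item is held; the
#' rank-weighted indices additionally reward early mention, on the view that
#' more culturally salient items come to mind first.
#'
#' The Smith index averages the rank-discounted weight over all N
#' respondents: \deqn{S_i = \frac{1}{N} \sum_{j: i \in list_j}
#' \frac{L_j - R_{ij} + 1}{L_j}} where \eqn{L_j} is the length of list j and
#' \eqn{R_{ij}} the 1-based rank of item i on it. The Sutrop index combines
#' frequency and mean rank: \deqn{T_i = \frac{F_i}{N \cdot mR_i}.} Both lie
#' in (0, 1], never exceed prevalence, and equal prevalence exactly when an
#' item is always mentioned first.
#'
#' The denominator N is the total number of respondents in the (sub)sample,
#' including any with empty lists, so all three measures share prevalence
#' semantics ("proportion of people that mentioned the item").
#'
#' @param data a \code{\link{freelist}} object.
#' @return data frame with columns \code{item}, \code{freq}, \code{p},
#'   \code{mean_rank}, \code{smith}, \code{sutrop}, sorted by descending
#'   \code{p} then item label.
#' @examples
#' fl <- freelist(list(c("x", "y", "z"), c("y", "x")))
#' salience_table(fl)
#' @export
salience_table <- function(data) {
  stopifnot(inherits(data, "freelist"))
  N <- n_respondents(data)
  long <- as.data.frame(data)
  if (nrow(long) == 0L) stop("empty dataset: no responses")
  L <- list_lengths(data)
  long$L <- L[long$respondent]
  by_item <- split(long, long$response)
  tab <- data.frame(
    item = names(by_item),
    freq = vapply(by_item, nrow, integer(1)),
    mean_rank = vapply(by_item, function(d) mean(d$order), numeric(1)),
    smith = vapply(by_item, function(d)
      sum((d$L - d$order + 1) / d$L) / N, numeric(1)),
    stringsAsFactors = FALSE, row.names = NULL
  )
  tab$p <- tab$freq / N
  tab$sutrop <- tab$freq / (N * tab$mean_rank)
  tab <- tab[order(-tab$p, tab$item), c("item", "freq", "p", "mean_rank",
                                        "smith", "sutrop")]
  row.names(tab) <- NULL
  tab
}

#' Smith salience index
#' @param data a \code{\link{freelist}} object.
#' @return named numeric vector of Smith scores per item.
#' @seealso \code{\link{salience_table}} for the definition.
#' @export
smith_index <- function(data) {
  tab <- salience_table(data)
  stats::setNames(tab$smith, tab$item)
}

#' Sutrop salience index
#' @param data a \code{\link{freelist}} object.
#' @return named numeric vector of Sutrop scores per item.
#' @seealso \code{\link{salience_table}} for the definition.
#' @export
sutrop_index <- function(data) {
  tab <- salience_table(data)
  stats::setNames(tab$sutrop, tab$item)
}

#' Correlations among salience measures
#'
#' Spearman and Pearson correlations among prevalence and the Smith and
#' Sutrop indices, restricted to items mentioned by at least
#' \code{min_frequency} respondents. The frequency filter removes the long
#' tail of items mentioned once, whose scores are dominated by a single
#' list.
#'
#' @param tab a salience table from \code{\link{salience_table}}, or a
#'   \code{freelist} object (the table is computed).
#' @param min_frequency minimum number of lists an item must appear on.
#' @return data frame with columns \code{pair}, \code{spearman},
#'   \code{pearson}; one row per unordered pair of \{p, smith, sutrop\}.
#' @export
salience_correlations <- function(tab, min_frequency = 2) {
  if (inherits(tab, "freelist")) tab <- salience_table(tab)
  keep <- tab[tab$freq >= min_frequency, , drop = FALSE]
  if (nrow(keep) < 3L)
    stop("fewer than 3 items pass the frequency filter")
  pairs <- list(c("smith", "sutrop"), c("smith", "p"), c("sutrop", "p"))
  out <- lapply(pairs, function(pr) {
    data.frame(
      pair = paste(pr, collapse = "-"),
      spearman = stats::cor(keep[[pr[1]]], keep[[pr[2]]],
                            method = "spearman"),
      pearson = stats::cor(keep[[pr[1]]], keep[[pr[2]]]),
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, out)
}

#' Salient-item reference set
#'
#' The set of items mentioned by at least a given proportion of the first
#' \code{reference_n} respondents with full (untruncated) listing. This is
#' the reference against which capture at smaller samples or with limited
#' probing is judged.
#'
#' @param data a \code{\link{freelist}} object with \code{N >= reference_n}.
#' @param threshold prevalence cut-off (default 0.20).
#' @param reference_n size of the reference subsample (default 20).
#' @return character vector of salient items.
#' @export
salient_set <- function(data, threshold = 0.20, reference_n = 20) {
  stopifnot(inherits(data, "freelist"))
  if (n_respondents(data) < reference_n)
    stop("dataset has fewer than 'reference_n' respondents")
  ref <- head_respondents(data, reference_n)
  tab <- salience_table(ref)
  tab$item[tab$p >= threshold]
}

#' Proportion of salient items captured by a (sub)sample
#'
#' What fraction of a reference salient-item set appears anywhere on the
#' first \code{n} lists, optionally truncated to \code{k} responses per
#' person. Monotone non-decreasing in both \code{n} and \code{k}.
#'
#' @param salient character vector of reference items (non-empty).
#' @param data a \code{\link{freelist}} object.
#' @param n number of leading respondents to use (\code{n <= N}).
#' @param k optional truncation depth; \code{NULL} means full lists.
#' @return proportion in [0, 1].
#' @export
capture_proportion <- function(salient, data, n, k = NULL) {
  stopifnot(inherits(data, "freelist"))
  if (length(salient) == 0L) stop("empty salient set")
  sub <- head_respondents(data, n)
  if (!is.null(k)) sub <- truncate_lists(sub, k)
  mean(salient %in% item_universe(sub))
}
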