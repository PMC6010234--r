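#' Normalise a response label
#'
#' Free-list data collected by hand contain spelling, case, and spacing
#' variants of the same item. Normalisation is deliberately conservative:
#' case fold, trim, collapse internal whitespace runs, then apply an
#' explicit synonym map if one is supplied. No fuzzy matching or stemming is
#' attempted, because silent merges would change item counts.
#'
#' @param raw character vector of raw labels.
#' @param synonyms optional named character vector, \code{c(variant =
#'   "canonical")}; keys are matched after normalisation. The map should be
#'   idempotent (canonical labels map to themselves or are absent).
#' @return character vector of canonical labels.
#' @examples
#' normalize_label("  Coca  Cola ")
#' normalize_label("Coke", synonyms = c(coke = "coca cola"))
#' @export
normalize_label <- function(raw, synonyms = NULL) {
  x <- tolower(trimws(as.character(raw)))
  x <- gsub("[[:space:]]+", " ", x)
  if (any(!nzchar(x)))
    stop("empty label after normalisation")
  if (!is.null(synonyms)) {
    key <- names(synonyms)
    if (is.null(key)) stop("'synonyms' must be a named character vector")
    hit <- match(x, key)
    x[!is.na(hit)] <- unname(synonyms[hit[!is.na(hit)]])
  }
  x
}

#' Read a free-list dataset in long format
#'
#' Long format is delimited text with a header containing at least
#' \code{respondent}, \code{order}, \code{response}; one row per mention.
#' Rows are sorted by \code{order} within respondent, and respondents keep
#' their first-appearance order in the file.
#'
#' @param path path to a delimited text file.
#' @param synonyms optional synonym map (see \code{\link{normalize_label}}).
#' @param domain domain label; defaults to the file name stem.
#' @param sep field separator.
#' @return a \code{\link{freelist}} object.
#' @export
read_freelist_long <- function(path, synonyms = NULL, domain = NULL,
                               sep = ",") {
  tab <- utils::read.table(path, header = TRUE, sep = sep, quote = "\"",
                           stringsAsFactors = FALSE, comment.char = "",
                           fileEncoding = "UTF-8")
  need <- c("respondent", "order", "response")
  if (!all(need %in% names(tab)))
    stop("missing required columns: ",
         paste(setdiff(need, names(tab)), collapse = ", "))
  if (nrow(tab) == 0L) stop("empty free-list file: ", path)
  if (anyDuplicated(tab[c("respondent", "order")]))
    stop("duplicate (respondent, order) pairs in ", path)
  ord <- suppressWarnings(as.integer(tab$order))
  if (anyNA(ord) || any(ord < 1L))
    stop("'order' values must be positive integers")
  ids <- as.character(tab$respondent)
  ids_first <- ids[!duplicated(ids)]
  lists <- lapply(split(data.frame(ord = ord, resp = tab$response,
                                   stringsAsFactors = FALSE),
                        factor(ids, levels = ids_first)),
                  function(d) d$resp[order(d$ord)])
  if (is.null(domain))
    domain <- sub("\\.[^.]*$", "", basename(path))
  freelist(lists, domain = domain, synonyms = synonyms)
}

#' Read a free-list dataset in wide format
#'
#' Wide format has one row per respondent: first column the respondent id,
#' remaining columns the responses in rank order, with trailing blanks
#' allowed. This matches the one-sheet-per-example layout of deposited
#' free-list workbooks once each sheet is exported to delimited text.
#'
#' @inheritParams read_freelist_long
#' @param header whether the file has a header row (ignored for content).
#' @return a \code{\link{freelist}} object.
#' @export
read_freelist_wide <- function(path, synonyms = NULL, domain = NULL,
                               sep = ",", header = FALSE) {
  tab <- utils::read.table(path, header = header, sep = sep, quote = "\"",
                           stringsAsFactors = FALSE, comment.char = "",
                           fill = TRUE, fileEncoding = "UTF-8",
                           colClasses = "character")
  if (nrow(tab) == 0L) stop("empty free-list file: ", path)
  ids <- as.character(tab[[1L]])
  lists <- lapply(seq_len(nrow(tab)), function(i) {
    x <- as.character(tab[i, -1L])
    x <- x[!is.na(x) & nzchar(trimws(x))]
    x
  })
  names(lists) <- ids
  if (is.null(domain))
    domain <- sub("\\.[^.]*$", "", basename(path))
  freelist(lists, domain = domain, synonyms = synonyms)
}

#' Write a free-list dataset in long format
#'
#' @param data a \code{freelist} object.
#' @param path output path.
#' @param sep field separator.
#' @return \code{path}, invisibly.
#' @export
write_freelist_long <- function(data, path, sep = ",") {
  stopifnot(inherits(data, "freelist"))
  utils::write.table(as.data.frame(data), path, sep = sep, row.names = FALSE,
                     quote = TRUE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a synonym map from delimited text
#'
#' Two columns, \code{variant} and \code{canonical}; both are normalised on
#' read so the map can be written in any case.
#'
#' @param path path to a delimited text file with a header.
#' @param sep field separator.
#' @return named character vector suitable for the \code{synonyms} argument
#'   of the readers.
#' @export
read_synonyms <- function(path, sep = ",") {
  tab <- utils::read.table(path, header = TRUE, sep = sep, quote = "\"",
                           stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  if (!all(c("variant", "canonical") %in% names(tab)))
    stop("synonym file needs 'variant' and 'canonical' columns")
  map <- stats::setNames(normalize_label(tab$canonical),
                         normalize_label(tab$variant))
  map
}

#' Read a directory of free-list examples
#'
#' Loads every long-format file in a directory as one example, returning a
#' named list of \code{freelist} objects. Used for corpus-level analyses
#' (one file per topical domain example).
#'
#' @param dir directory containing \code{.csv} long-format files.
#' @param synonyms optional synonym map applied to every example.
#' @param pattern file-name pattern.
#' @return named list of \code{freelist} objects.
#' @export
read_freelist_corpus <- function(dir, synonyms = NULL, pattern = "\\.csv$") {
  if (!dir.exists(dir)) stop("corpus directory not found: ", dir)
  files <- list.files(dir, pattern = pattern, full.names = TRUE)
  if (length(files) == 0L) stop("no free-list files in ", dir)
  out <- lapply(files, read_freelist_long, synonyms = synonyms)
  names(out) <- vapply(out, function(x) x$domain, character(1))
  out
}
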