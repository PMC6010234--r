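# random small datasets built independently of the package simulator, for
# oracle comparisons
random_lists <- function(N, D = 12, max_L = 8, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  items <- letters[seq_len(D)]
  lapply(seq_len(N), function(i) {
    L <- sample.int(max_L, 1)
    sample(items, min(L, D), replace = FALSE)
  })
}

random_freelist <- function(N, D = 12, max_L = 8, seed = NULL) {
  freelist(random_lists(N, D, max_L, seed), normalize = FALSE)
}

# naive per-item loop oracles for the salience indices
smith_oracle <- function(lists, N = length(lists)) {
  items <- unique(unlist(lists))
  vapply(stats::setNames(items, items), function(it) {
    w <- vapply(lists, function(l) {
      r <- match(it, l)
      if (is.na(r)) 0 else (length(l) - r + 1) / length(l)
    }, numeric(1))
    sum(w) / N
  }, numeric(1))
}

sutrop_oracle <- function(lists, N = length(lists)) {
  items <- unique(unlist(lists))
  vapply(stats::setNames(items, items), function(it) {
    ranks <- unlist(lapply(lists, function(l) match(it, l)))
    ranks <- ranks[!is.na(ranks)]
    length(ranks) / (N * mean(ranks))
  }, numeric(1))
}

# brute-force prefix set-union accumulation oracle
accumulation_oracle <- function(lists) {
  vapply(seq_along(lists), function(n)
    length(unique(unlist(lists[seq_len(n)]))), integer(1))
}

# build a capture_spectrum object directly from an f vector
make_spectrum <- function(f, t = length(f)) {
  f <- c(f, rep(0L, t - length(f)))
  structure(list(t = t, S = sum(f), f = as.integer(f)),
            class = "capture_spectrum")
}

# write a long-format csv for reader tests
write_long_csv <- function(df, path = tempfile(fileext = ".csv")) {
  utils::write.csv(df, path, row.names = FALSE)
  path
}
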