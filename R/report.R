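#' Full analysis report for a corpus of free-list examples
#'
#' Orchestrates the whole pipeline over one or more examples: per-example
#' salience tables and new-item series, saturation model fits and derived
#' quantities, capture-recapture domain-size estimates, the truncation
#' experiment, and corpus-level aggregates. Optionally writes every table
#' as delimited text into an output directory. All analysis steps are
#' deterministic; the only randomness in the package lives in the
#' simulator, behind explicit seeds.
#'
#' @param datasets named list of \code{\link{freelist}} objects (e.g. from
#'   \code{\link{read_freelist_corpus}} or \code{\link{simulate_corpus}}).
#' @param output_dir optional directory for delimited-text outputs.
#' @param saturation_thresholds thresholds passed to
#'   \code{\link{batch_saturation}}.
#' @param k truncation depth for the limited-probing comparison.
#' @param salience_threshold,reference_n salient-set parameters.
#' @return list with \code{saturation} (per-example table + summary),
#'   \code{domain_size} (capture-recapture estimates per example),
#'   \code{salience_correlations} (per example + mean), \code{truncation}
#'   (from \code{\link{batch_truncation}}).
#' @export
analyze_corpus <- function(datasets, output_dir = NULL,
                           saturation_thresholds = c(1, 2), k = 3,
                           salience_threshold = 0.20, reference_n = 20) {
  stopifnot(length(datasets) >= 1L)
  sat <- batch_saturation(datasets, thresholds = saturation_thresholds)

  dom <- do.call(rbind, lapply(names(datasets), function(nm) {
    est <- tryCatch(best_domain_estimate(capture_spectrum(datasets[[nm]])),
                    error = function(e) NULL)
    data.frame(example = nm,
               model = if (is.null(est)) NA_character_ else est$model,
               abundance = if (is.null(est)) NA_real_
                           else round(est$abundance, 1),
               stringsAsFactors = FALSE)
  }))

  cors <- do.call(rbind, lapply(names(datasets), function(nm) {
    cc <- tryCatch(salience_correlations(datasets[[nm]]),
                   error = function(e) NULL)
    if (is.null(cc)) return(NULL)
    cbind(example = nm, cc)
  }))
  mean_cors <- if (!is.null(cors))
    stats::aggregate(cbind(spearman, pearson) ~ pair, data = cors, FUN = mean)
  else NULL

  trunc <- batch_truncation(datasets, k = k,
                            salience_threshold = salience_threshold,
                            reference_n = reference_n)

  out <- list(saturation = sat, domain_size = dom,
              salience_correlations = list(per_example = cors,
                                           mean = mean_cors),
              truncation = trunc)

  if (!is.null(output_dir)) {
    dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
    wr <- function(x, name)
      utils::write.table(x, file.path(output_dir, paste0(name, ".tsv")),
                         sep = "\t", row.names = FALSE, quote = FALSE)
    wr(sat$table, "saturation_table")
    wr(sat$summary, "saturation_summary")
    wr(dom, "domain_size_estimates")
    if (!is.null(cors)) wr(cors, "salience_correlations")
    if (!is.null(mean_cors)) wr(mean_cors, "salience_correlations_mean")
    wr(trunc$table, "truncation_table")
    for (nm in names(datasets)) {
      wr(salience_table(datasets[[nm]]),
         paste0("salience_", gsub("[^A-Za-z0-9_-]", "_", nm)))
      wr(new_item_series(datasets[[nm]]),
         paste0("series_", gsub("[^A-Za-z0-9_-]", "_", nm)))
    }
  }
  out
}
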