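#' Fit competing accumulation models to a new-item series
#'
#' The expected number of new items contributed by the x-th respondent is
#' modelled as a function of sample size x with generalized linear models:
#' ordinary least squares (normal, identity link), Poisson log link, and
#' negative binomial with log and identity links. Counts of new items are
#' approximately Poisson, but real series are overdispersed with a long
#' tail, which the negative binomial absorbs through its dispersion
#' parameter (estimated by maximum likelihood; a moment estimate is used as
#' fallback when ML fails).
#'
#' @param series a data frame from \code{\link{new_item_series}} (columns
#'   \code{n}, \code{new_items}), of length at least 3.
#' @return list of candidate fits (class \code{"saturation_fit"} each), in
#'   the tie-break preference order nb-log, poisson-log, nb-identity,
#'   normal-identity. Candidates that fail to converge carry
#'   \code{converged = FALSE} and are retained for reporting.
#' @export
fit_accumulation_models <- function(series) {
  stopifnot(is.data.frame(series),
            all(c("n", "new_items") %in% names(series)))
  if (nrow(series) < 3L) stop("series too short to fit (need >= 3 points)")
  d <- data.frame(x = series$n, y = series$new_items)

  mk <- function(family, link, fitter) {
    fit <- tryCatch(suppressWarnings(fitter()), error = function(e) e)
    if (inherits(fit, "error"))
      return(structure(list(family = family, link = link, converged = FALSE,
                            error = conditionMessage(fit), aic = Inf),
                       class = "saturation_fit"))
    cf <- stats::coef(fit)
    structure(list(
      family = family, link = link, converged = TRUE,
      b0 = unname(cf[1]), b1 = unname(cf[2]),
      dispersion = if (family == "negative_binomial") fit$theta else NULL,
      aic = stats::AIC(fit),
      slope_p = tryCatch(summary(fit)$coefficients[2, 4],
                         error = function(e) NA_real_),
      model = fit
    ), class = "saturation_fit")
  }

  nb_log <- mk("negative_binomial", "log", function() {
    fit <- MASS::glm.nb(y ~ x, data = d)
    if (!fit$converged) stop("glm.nb did not converge")
    fit
  })
  if (!nb_log$converged) {
    # moment fallback: theta from Poisson-fit residual overdispersion
    nb_log <- mk("negative_binomial", "log", function() {
      pf <- stats::glm(y ~ x, family = stats::poisson(), data = d)
      mu <- stats::fitted(pf)
      excess <- sum((d$y - mu)^2 - mu)
      if (excess <= 0) stop("no overdispersion; moment theta undefined")
      theta <- sum(mu^2) / excess
      stats::glm(y ~ x, family = MASS::negative.binomial(theta), data = d)
    })
    if (nb_log$converged) nb_log$dispersion_method <- "moment"
  }

  pois_log <- mk("poisson", "log", function()
    stats::glm(y ~ x, family = stats::poisson(), data = d))

  nb_ident <- mk("negative_binomial", "identity", function() {
    ls_fit <- stats::lm(y ~ x, data = d)
    fit <- MASS::glm.nb(y ~ x, data = d, link = identity,
                        mustart = pmax(stats::fitted(ls_fit), 0.5))
    if (!fit$converged) stop("glm.nb (identity) did not converge")
    if (any(stats::fitted(fit) <= 0)) stop("identity fit crosses zero")
    fit
  })

  norm_ident <- mk("normal", "identity", function()
    stats::glm(y ~ x, family = stats::gaussian(), data = d))

  list(nb_log = nb_log, poisson_log = pois_log, nb_identity = nb_ident,
       normal_identity = norm_ident)
}

#' @export
print.saturation_fit <- function(x, ...) {
  if (!x$converged) {
    cat(sprintf("saturation fit %s (%s link): failed (%s)\n",
                x$family, x$link, x$error))
  } else {
    cat(sprintf("saturation fit %s (%s link): b0 = %.4f, b1 = %.4f, AIC = %.2f\n",
                x$family, x$link, x$b0, x$b1, x$aic))
  }
  invisible(x)
}

#' Select the best accumulation model by AIC
#'
#' Minimum AIC among converged candidates; ties resolved deterministically
#' in the order nb-log, poisson-log, nb-identity, normal-identity.
#'
#' @param candidates list from \code{\link{fit_accumulation_models}}.
#' @return the winning \code{saturation_fit}.
#' @export
select_best_fit <- function(candidates) {
  pref <- c("nb_log", "poisson_log", "nb_identity", "normal_identity")
  candidates <- candidates[intersect(pref, names(candidates))]
  ok <- vapply(candidates, function(f) isTRUE(f$converged), logical(1))
  if (!any(ok)) stop("no accumulation model converged")
  aics <- vapply(candidates, function(f) f$aic, numeric(1))
  aics[!ok] <- Inf
  best <- candidates[[which.min(aics)]]
  best$label <- names(candidates)[which.min(aics)]
  best
}

#' Predicted new items at sample size x
#' @param fit a converged \code{saturation_fit}.
#' @param x sample size(s).
#' @return expected new-item count(s) on the response scale.
#' @export
predict_new_items <- function(fit, x) {
  stopifnot(inherits(fit, "saturation_fit"), isTRUE(fit$converged))
  eta <- fit$b0 + fit$b1 * x
  if (fit$link == "log") exp(eta) else eta
}

#' Saturation point of a fitted accumulation curve
#'
#' Saturation is defined as the sample size beyond which each additional
#' respondent is expected to contribute at most \code{threshold} new items
#' (default one). The fitted curve is solved for
#' \eqn{\hat Y(x) = threshold} and rounded up to the next integer. A
#' non-negative slope means the curve never descends to the threshold and
#' saturation is reported as not reached.
#'
#' @param fit a converged \code{saturation_fit}.
#' @param threshold expected new items per additional respondent (1 is the
#'   strict rule; 2 a more liberal one).
#' @return list with \code{x_continuous} (the continuous solution, reported
#'   to 2 decimals), \code{n_sat} (integer sample size), and
#'   \code{reached} (FALSE when the slope is non-negative, in which case the
#'   other fields are NA).
#' @export
saturation_point <- function(fit, threshold = 1.0) {
  stopifnot(inherits(fit, "saturation_fit"), isTRUE(fit$converged))
  not_reached <- list(x_continuous = NA_real_, n_sat = NA_integer_,
                      reached = FALSE)
  if (fit$b1 >= 0) return(not_reached)
  xc <- if (fit$link == "log") (log(threshold) - fit$b0) / fit$b1
        else (threshold - fit$b0) / fit$b1
  # a numerically flat curve (b1 just below 0) never descends in practice
  if (!is.finite(xc) || xc > 1e9) return(not_reached)
  n_sat <- if (predict_new_items(fit, 1) <= threshold) 1L
           else as.integer(ceiling(xc))
  list(x_continuous = round(xc, 2), n_sat = max(1L, n_sat), reached = TRUE)
}

#' Predicted unique items accumulated by the point of saturation
#'
#' Sums the fitted per-respondent yields \eqn{\hat Y(x)} for x = 1 ..
#' n_sat on the fitted (continuous) scale. Identity-link predictions are
#' clamped at zero so a descending line cannot subtract items.
#'
#' @param fit a converged \code{saturation_fit}.
#' @param n_sat saturation sample size (from \code{\link{saturation_point}}).
#' @return expected unique-item count at saturation.
#' @export
domain_at_saturation <- function(fit, n_sat) {
  stopifnot(inherits(fit, "saturation_fit"), isTRUE(fit$converged))
  if (is.na(n_sat)) return(NA_real_)
  yhat <- predict_new_items(fit, seq_len(n_sat))
  if (fit$link == "identity") yhat <- pmax(yhat, 0)
  sum(yhat)
}

#' Total domain size extrapolated to an infinite sample
#'
#' For a log-link fit with negative slope the per-respondent yields form a
#' geometric series with ratio \eqn{r = e^{b_1} < 1}, so the total converges
#' in closed form to \deqn{D_{tot} = e^{b_0} \frac{r}{1 - r}.} For an
#' identity link the line is summed (clamped at zero) up to its
#' zero-crossing. A non-negative slope gives no finite total.
#'
#' @param fit a converged \code{saturation_fit}.
#' @return estimated total domain size, or NA when the series diverges.
#' @export
total_domain_size <- function(fit) {
  stopifnot(inherits(fit, "saturation_fit"), isTRUE(fit$converged))
  if (fit$b1 >= 0) return(NA_real_)
  if (fit$link == "log") {
    r <- exp(fit$b1)
    exp(fit$b0) * r / (1 - r)
  } else {
    x_zero <- floor(-fit$b0 / fit$b1)
    if (x_zero < 1) return(0)
    sum(pmax(fit$b0 + fit$b1 * seq_len(x_zero), 0))
  }
}

#' Probability an idea of given prevalence appears at least once
#'
#' Binomial design calculator: with independent respondents and an idea
#' held by a proportion p of the population, the chance of seeing it at
#' least once in n interviews is \eqn{1 - (1-p)^n}. Salience heterogeneity
#' makes real lists non-independent, so this is a planning floor, not a
#' guarantee.
#'
#' @param p prevalence in (0, 1].
#' @param n number of interviews (>= 1).
#' @return probability in (0, 1].
#' @examples
#' p_at_least_once(0.2, 14)   # ~0.956
#' @export
p_at_least_once <- function(p, n) {
  if (any(p <= 0 | p > 1)) stop("'p' must be in (0, 1]")
  if (any(n < 1)) stop("'n' must be >= 1")
  1 - (1 - p)^n
}

#' Interviews needed to see an idea with given confidence
#'
#' Inverts \code{\link{p_at_least_once}}: the smallest integer n with
#' \eqn{1 - (1-p)^n \ge confidence}.
#'
#' @param p prevalence in (0, 1).
#' @param confidence target probability in (0, 1).
#' @return minimal integer sample size.
#' @examples
#' n_for_confidence(0.2, 0.95)  # 14
#' n_for_confidence(0.2, 0.90)  # 11
#' @export
n_for_confidence <- function(p, confidence) {
  if (any(p <= 0 | p >= 1)) stop("'p' must be in (0, 1)")
  if (any(confidence <= 0 | confidence >= 1))
    stop("'confidence' must be in (0, 1)")
  n <- ceiling(log(1 - confidence) / log(1 - p))
  # guard against representation error at exact solutions
  n <- ifelse(p_at_least_once(p, pmax(n - 1, 1)) >= confidence &
                n - 1 >= 1, n - 1, n)
  as.integer(pmax(n, 1))
}

#' Saturation analysis for one dataset
#'
#' Convenience wrapper: builds the new-item series, fits and selects the
#' accumulation model, and derives the saturation point, domain size at
#' saturation, and total domain size.
#'
#' @param data a \code{\link{freelist}} object.
#' @param threshold saturation threshold (expected new items).
#' @return list with \code{series}, \code{candidates}, \code{fit},
#'   \code{saturation} (from \code{\link{saturation_point}}), \code{d_sat},
#'   \code{d_tot}.
#' @export
saturation_analysis <- function(data, threshold = 1.0) {
  series <- new_item_series(data)
  cands <- fit_accumulation_models(series)
  fit <- select_best_fit(cands)
  sat <- saturation_point(fit, threshold)
  list(series = series, candidates = cands, fit = fit, saturation = sat,
       d_sat = domain_at_saturation(fit, sat$n_sat),
       d_tot = total_domain_size(fit))
}

#' Batch saturation analysis over a corpus of examples
#'
#' Produces one summary row per example (sample size, mean and range of
#' list length, unique items, best model, saturation sample size at the
#' strict and liberal thresholds, domain sizes) plus corpus-level medians
#' and ranges of the saturation sample sizes.
#'
#' @param datasets named list of \code{\link{freelist}} objects.
#' @param thresholds numeric vector of saturation thresholds.
#' @return list with \code{table} (per-example data frame) and
#'   \code{summary} (data frame of median and range of n_sat per threshold,
#'   over examples where saturation is reached).
#' @export
batch_saturation <- function(datasets, thresholds = c(1, 2)) {
  stopifnot(length(datasets) >= 1L)
  rows <- lapply(names(datasets), function(nm) {
    fl <- datasets[[nm]]
    L <- list_lengths(fl)
    ana <- saturation_analysis(fl, threshold = thresholds[1])
    row <- data.frame(
      example = nm, N = n_respondents(fl), mean_L = round(mean(L), 1),
      min_L = min(L), max_L = max(L),
      unique_items = length(item_universe(fl)),
      best_model = ana$fit$label,
      stringsAsFactors = FALSE
    )
    for (th in thresholds) {
      sat <- saturation_point(ana$fit, th)
      row[[paste0("n_sat_y", th)]] <- sat$n_sat
      row[[paste0("d_sat_y", th)]] <-
        round(domain_at_saturation(ana$fit, sat$n_sat), 1)
    }
    row$d_tot <- round(ana$d_tot, 1)
    row
  })
  tab <- do.call(rbind, rows)
  summ <- do.call(rbind, lapply(thresholds, function(th) {
    v <- tab[[paste0("n_sat_y", th)]]
    v <- v[!is.na(v)]
    data.frame(threshold = th, n_examples = length(v),
               median_n_sat = stats::median(v),
               min_n_sat = if (length(v)) min(v) else NA,
               max_n_sat = if (length(v)) max(v) else NA)
  }))
  list(table = tab, summary = summ)
}
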