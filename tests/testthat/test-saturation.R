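test_that("log-link fits recover known generating coefficients", {
  x <- 1:40
  series <- data.frame(n = x, new_items = round(exp(2 - 0.1 * x)))
  cands <- fit_accumulation_models(series)
  expect_equal(cands$nb_log$b1, -0.1, tolerance = 0.2)
  expect_equal(cands$poisson_log$b1, -0.1, tolerance = 0.2)
  expect_equal(cands$poisson_log$b0, 2, tolerance = 0.1)
  expect_true(all(c("nb_log", "poisson_log", "nb_identity",
                    "normal_identity") %in% names(cands)))
})

test_that("a flat series yields no saturation point", {
  series <- data.frame(n = 1:20, new_items = rep(4L, 20))
  best <- select_best_fit(fit_accumulation_models(series))
  expect_lt(abs(best$b1), 1e-6)
  sat <- saturation_point(best)
  expect_false(sat$reached)
  expect_true(is.na(sat$n_sat))
})

test_that("model selection minimises AIC with a fixed tie-break order", {
  f <- function(label, aic) structure(
    list(family = "poisson", link = "log", b0 = 1, b1 = -0.1,
         converged = TRUE, aic = aic),
    class = "saturation_fit")
  single <- select_best_fit(list(poisson_log = f("p", 100)))
  expect_equal(single$label, "poisson_log")
  two <- select_best_fit(list(nb_log = f("nb", 101), poisson_log = f("p", 100)))
  expect_equal(two$label, "poisson_log")
  # exact tie goes to the preferred family order
  tie <- select_best_fit(list(poisson_log = f("p", 100), nb_log = f("nb", 100)))
  expect_equal(tie$label, "nb_log")
  expect_error(select_best_fit(list(a = structure(
    list(converged = FALSE, aic = Inf), class = "saturation_fit"))),
    "no accumulation model converged")
})

test_that("saturation point solves the fitted curve in closed form", {
  fit <- structure(list(family = "poisson", link = "log", b0 = 3,
                        b1 = -0.25, converged = TRUE),
                   class = "saturation_fit")
  sat <- saturation_point(fit, threshold = 1)
  expect_equal(sat$x_continuous, 12)
  expect_equal(sat$n_sat, 12L)
  # already below threshold at x = 1
  low <- structure(list(family = "poisson", link = "log", b0 = 0,
                        b1 = -0.5, converged = TRUE),
                   class = "saturation_fit")
  expect_equal(saturation_point(low, 1)$n_sat, 1L)
  # identity-link solution
  ident <- structure(list(family = "normal", link = "identity", b0 = 10,
                          b1 = -1.5, converged = TRUE),
                     class = "saturation_fit")
  expect_equal(saturation_point(ident, 1)$x_continuous, 6)
  expect_equal(saturation_point(ident, 1)$n_sat, 6L)
  # rising curve never saturates
  rising <- structure(list(family = "poisson", link = "log", b0 = 1,
                           b1 = 0.1, converged = TRUE),
                      class = "saturation_fit")
  expect_false(saturation_point(rising)$reached)
})

test_that("saturation size grows and sample size shrinks with a looser threshold", {
  fit <- structure(list(family = "poisson", link = "log", b0 = 3.2,
                        b1 = -0.12, converged = TRUE),
                   class = "saturation_fit")
  s1 <- saturation_point(fit, 1); s2 <- saturation_point(fit, 2)
  expect_lte(s2$n_sat, s1$n_sat)
  expect_gte(domain_at_saturation(fit, s1$n_sat),
             domain_at_saturation(fit, s2$n_sat))
})

test_that("geometric-series domain size matches numeric summation", {
  # predicted yields 0.5^x: total domain is exactly 1
  half <- structure(list(family = "poisson", link = "log", b0 = 0,
                         b1 = log(0.5), converged = TRUE),
                    class = "saturation_fit")
  expect_equal(total_domain_size(half), 1.0)
  expect_equal(domain_at_saturation(half, 1), 0.5)

  for (b1 in c(-0.05, -0.2, -1)) {
    fit <- structure(list(family = "poisson", link = "log", b0 = 2.4,
                          b1 = b1, converged = TRUE),
                     class = "saturation_fit")
    r <- exp(b1)
    n <- 20
    # partial geometric sum, closed form vs numeric
    expect_equal(domain_at_saturation(fit, n),
                 exp(2.4) * (r - r^(n + 1)) / (1 - r), tolerance = 1e-9)
    # infinite sum vs numeric summation to 1e6 terms
    expect_equal(total_domain_size(fit),
                 sum(exp(2.4 + b1 * seq_len(1e6))), tolerance = 1e-6)
  }
  # identity link: clamped sum to the zero crossing
  ident <- structure(list(family = "normal", link = "identity", b0 = 5,
                          b1 = -1, converged = TRUE),
                     class = "saturation_fit")
  expect_equal(total_domain_size(ident), 4 + 3 + 2 + 1 + 0)
})

test_that("binomial design calculators match their closed forms", {
  expect_equal(p_at_least_once(1, 3), 1.0)
  expect_equal(p_at_least_once(0.2, 14), 1 - 0.8^14)
  expect_gte(p_at_least_once(0.2, 14), 0.95)
  expect_equal(p_at_least_once(0.2, 11), 0.914, tolerance = 1e-3)
  expect_error(p_at_least_once(0, 5), "must be in")

  expect_equal(n_for_confidence(0.2, 0.95), 14L)
  expect_equal(n_for_confidence(0.2, 0.90), 11L)
  expect_equal(n_for_confidence(0.5, 0.5), 1L)
  expect_error(n_for_confidence(1, 0.9), "must be in")
  # inversion consistency on a grid
  for (p in c(0.05, 0.1, 0.3, 0.7)) for (cf in c(0.5, 0.8, 0.99)) {
    n <- n_for_confidence(p, cf)
    expect_gte(p_at_least_once(p, n), cf)
    if (n > 1) expect_lt(p_at_least_once(p, n - 1), cf)
  }
})

test_that("Poisson and negative binomial coincide on near-Poisson series", {
  set.seed(31)
  x <- 1:35
  series <- data.frame(n = x, new_items = rpois(35, exp(2.5 - 0.08 * x)))
  cands <- fit_accumulation_models(series)
  expect_true(cands$poisson_log$converged)
  if (cands$nb_log$converged) {
    expect_equal(predict_new_items(cands$nb_log, x),
                 predict_new_items(cands$poisson_log, x), tolerance = 0.05)
  }
})

test_that("batch analysis summarises a corpus with medians and ranges", {
  corpus <- lapply(c(3, 14, 25), function(sd)
    simulate_freelist(D = 80, N = 30, mean_length = 12, s = 1, seed = sd))
  names(corpus) <- paste0("ex", seq_along(corpus))
  out <- batch_saturation(corpus, thresholds = c(1, 2))
  expect_equal(nrow(out$table), 3L)
  expect_true(all(c("n_sat_y1", "n_sat_y2", "d_tot", "best_model")
                  %in% names(out$table)))
  expect_equal(out$summary$median_n_sat[out$summary$threshold == 1],
               median(out$table$n_sat_y1))
  # looser threshold saturates no later, example by example
  ok <- !is.na(out$table$n_sat_y1) & !is.na(out$table$n_sat_y2)
  expect_true(all(out$table$n_sat_y2[ok] <= out$table$n_sat_y1[ok]))
})

test_that("model-based totals approach the true domain size as N grows", {
  meds <- vapply(c(15, 60), function(N) {
    est <- vapply(1:8, function(sd) {
      fl <- simulate_freelist(D = 60, N = N, mean_length = 12, s = 0.5,
                              seed = 300 + sd * 7 + N)
      tryCatch(total_domain_size(select_best_fit(
        fit_accumulation_models(new_item_series(fl)))),
        error = function(e) NA_real_)
    }, numeric(1))
    median(abs(est - 60), na.rm = TRUE)
  }, numeric(1))
  expect_lt(meds[2], meds[1])
})
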