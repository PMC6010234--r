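test_that("two-respondent estimate follows the Lincoln-Petersen product", {
  expect_equal(two_sample_estimate(15, 31, 5), 93)
  expect_equal(two_sample_estimate(7, 7, 7), 7)     # identical lists
  expect_equal(two_sample_estimate(10, 10, 2), 50)
  expect_warning(out <- two_sample_estimate(4, 5, 0), "undefined")
  expect_true(is.na(out))
  expect_error(two_sample_estimate(0, 5, 1), ">= 1")
})

test_that("capture spectrum counts items by number of lists containing them", {
  same <- freelist(rep(list(paste0("i", 1:6)), 4), normalize = FALSE)
  sp <- capture_spectrum(same)
  expect_equal(sp$f[4], 6L)
  expect_equal(sum(sp$f), 6L)

  disjoint <- freelist(lapply(1:3, function(i) paste0("r", i, "_", 1:4)),
                       normalize = FALSE)
  expect_equal(capture_spectrum(disjoint)$f[1], 12L)

  for (seed in 1:6) {
    fl <- random_freelist(7, seed = 400 + seed)
    sp <- capture_spectrum(fl)
    # brute force per-item occurrence counts
    occ <- table(table(unlist(fl$respondents)))
    expect_equal(sp$f[as.integer(names(occ))], as.integer(occ))
    # spectrum identities
    expect_equal(sum(sp$f), sp$S)
    expect_equal(sum(seq_len(sp$t) * sp$f), sum(list_lengths(fl)))
  }
})

test_that("Chao lower-bound GLM equals its two-point closed form", {
  set.seed(5)
  for (i in 1:10) {
    t <- sample(5:25, 1)
    f <- rpois(t, pmax(20 * exp(-0.7 * seq_len(t)), 0.05))
    f[1] <- f[1] + 5  # ensure singletons
    f[2] <- max(f[2], 1)
    sp <- make_spectrum(f, t)
    est <- fit_closed_population(sp, "Mh_chao_lb")
    closed <- f[1]^2 * (t - 1) / (2 * t * f[2])
    expect_equal(est$f0_hat, closed, tolerance = 1e-6)
    expect_equal(est$abundance, sp$S + closed, tolerance = 1e-6)
  }
})

test_that("degenerate spectra use the documented Chao fallbacks", {
  # no singletons: the lower bound adds nothing
  sp <- make_spectrum(c(0, 4, 3, 1), t = 6)
  est <- fit_closed_population(sp, "Mh_chao_lb")
  expect_equal(est$f0_hat, 0)
  expect_equal(est$abundance, sp$S)
  # no doubletons: bias-corrected moment form
  sp2 <- make_spectrum(c(5, 0, 2), t = 4)
  est2 <- fit_closed_population(sp2, "Mh_chao_lb")
  expect_equal(est2$f0_hat, 5 * 4 * 3 / (2 * 4))
  expect_match(est2$note, "bias-corrected")
})

test_that("abundance never falls below the observed item count", {
  for (seed in 1:5) {
    fl <- simulate_freelist(D = 80, N = 25, mean_length = 10, s = 1,
                            seed = 500 + seed)
    sp <- capture_spectrum(fl)
    best <- best_domain_estimate(sp)
    for (cand in best$candidates) {
      if (isTRUE(cand$converged) && is.finite(cand$abundance))
        expect_gte(cand$abundance, sp$S)
    }
  }
})

test_that("the homogeneous model recovers domain size on binomial spectra", {
  # direct binomial simulation, independent of the list generator:
  # D items each captured on Binomial(t, p) of t occasions
  D <- 100; t <- 12; p <- 0.15
  set.seed(99)
  est <- replicate(100, {
    caps <- rbinom(D, t, p)
    caps <- caps[caps > 0]
    sp <- make_spectrum(tabulate(caps, nbins = t), t)
    fit_closed_population(sp, "M0")$abundance
  })
  expect_equal(median(est, na.rm = TRUE), D, tolerance = 0.1)
})

test_that("model choice tracks the generating heterogeneity", {
  # homogeneous capture: M0 competitive with the Mh family (median AIC gap < 2)
  D <- 80; t <- 10; p <- 0.2
  set.seed(7)
  gaps <- replicate(30, {
    caps <- rbinom(D, t, p)
    sp <- make_spectrum(tabulate(caps[caps > 0], nbins = t), t)
    best <- best_domain_estimate(sp)
    aics <- vapply(best$candidates, function(x)
      if (isTRUE(x$converged) && !is.na(x$aic)) x$aic else Inf, numeric(1))
    aics["M0"] - min(aics)
  })
  expect_lt(median(gaps), 2)

  # long-tailed salience: an Mh variant beats M0
  set.seed(8)
  wins <- replicate(20, {
    fl <- simulate_freelist(D = 120, N = 30, mean_length = 12, s = 1.1,
                            seed = sample.int(1e6, 1))
    best <- best_domain_estimate(capture_spectrum(fl))
    best$model != "M0"
  })
  expect_gt(mean(wins), 0.5)
})

test_that("gamma heterogeneity estimates exceed the Chao bound on heavy tails", {
  set.seed(21)
  ratios <- replicate(15, {
    fl <- simulate_freelist(D = 200, N = 25, mean_length = 10, s = 1.2,
                            seed = sample.int(1e6, 1))
    sp <- capture_spectrum(fl)
    chao <- fit_closed_population(sp, "Mh_chao_lb")$abundance
    gam <- fit_closed_population(sp, "Mh_gamma")$abundance
    gam / chao
  })
  expect_gte(median(ratios, na.rm = TRUE), 1)
})

test_that("a single-item domain is estimated as a single item", {
  fl <- simulate_freelist(D = 1, N = 5, mean_length = 3, seed = 2)
  sp <- capture_spectrum(fl)
  expect_equal(fit_closed_population(sp, "Mh_chao_lb")$abundance, 1)
  expect_equal(best_domain_estimate(sp)$abundance, 1, tolerance = 1e-6)
})
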