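# Posterior-predictive machinery, driven from a point posterior at the
# published generating values (so oracles are exact).

truth_fit <- point_posterior(population_params(), "tlc")

test_that("with no uncertainty sources the prediction is the regression line", {
  p <- predictive_tlc(truth_fit, tlc_f = 4, load = 0, sources = character(),
                      n_sim = 100, seed = 1)
  expect_equal(unique(p$samples), 0.33 + 0.36 * 4)
  p1 <- predictive_tlc(truth_fit, tlc_f = 4, load = 1, sources = character(),
                       n_sim = 10, seed = 1)
  expect_equal(unique(p1$samples), 0.33 + 0.36 * 4 - 0.10 - 0.01 * 4)
})

test_that("predictive spread increases with failure criticality", {
  sds <- vapply(seq(2, 15, by = 1), function(f)
    predictive_tlc(truth_fit, f, 0, n_sim = 20000, seed = 42)$summary$sd,
    numeric(1))
  expect_true(all(diff(sds) > 0))
})

test_that("full-source prediction matches a brute-force re-simulation", {
  set.seed(9)
  n <- 50000
  pop <- population_params()
  # brute force: draw drivers flat, then truncated trial draws
  eff <- draw_participants(pop, n)
  ms <- trial_mu_sigma(eff, 5, 0)
  cap <- pnorm((5 - ms$mu) / ms$sigma)
  brute <- ms$mu + ms$sigma * qnorm(runif(n) * cap)
  p <- predictive_tlc(truth_fit, 5, 0, n_sim = n, seed = 10)
  se <- sd(brute) / sqrt(n)
  expect_lt(abs(mean(p$samples) - mean(brute)), 3 * sqrt(2) * se)
  expect_lt(abs(sd(p$samples) - sd(brute)), 3 * sqrt(2) * se)
  # and the marginal distributions agree (two-sample KS)
  ks <- suppressWarnings(ks.test(p$samples[1:10000], brute[1:10000]))
  expect_gt(ks$p.value, 0.01)
})

test_that("predictive bands nest and cover the mean", {
  p <- predictive_tlc(truth_fit, 8, 1, n_sim = 20000, seed = 3)$summary
  expect_lte(p$lo_95, p$lo_68)
  expect_lte(p$lo_68, p$mean)
  expect_lte(p$mean, p$hi_68)
  expect_lte(p$hi_68, p$hi_95)
})

test_that("CV decomposition attributes variance sequentially and exactly", {
  cv <- cv_decompose(truth_fit, n_sim = 20000, seed = 4)
  expect_equal(cv$within + cv$between + cv$estimation, cv$total)
  expect_true(all(cv$within >= 0 & cv$between >= 0))
  # a point posterior has no estimation uncertainty
  expect_equal(cv$estimation, rep(0, nrow(cv)), tolerance = 1e-12)
  # without load, within-participant variability is the largest component
  # (under load, the extra uncorrelated load random effects bring the
  # between component level with it; see the methods vignette)
  cv0 <- cv[cv$load == 0, ]
  expect_gt(cv0$within, cv0$between)
  expect_gt(cv0$within, cv0$estimation)
  # no between-participant SDs -> no between component
  pop0 <- population_params(sd_beta = rep(0, 4), sd_alpha = rep(0, 3))
  cv0 <- cv_decompose(point_posterior(pop0, "tlc"), n_sim = 5000, seed = 5)
  expect_equal(cv0$between, rep(0, 2), tolerance = 1e-10)
})

test_that("road-departure risk behaves like a survival curve should", {
  # closed-form driver-level mass agrees with trial-level simulation
  set.seed(6)
  pe <- p_exit(truth_fit, tlc_f = 2, load = 0, n_drivers = 2000, seed = 7)
  eff1 <- draw_participants(population_params(), 1, seed = 8)
  ms <- trial_mu_sigma(eff1, 2, 0)
  cap <- pnorm((2 - ms$mu) / ms$sigma)
  draws <- ms$mu + ms$sigma * qnorm(runif(1e5) * cap)
  sim_p <- mean(draws < 0.5)
  closed <- pnorm((0.5 - ms$mu) / ms$sigma) / cap
  expect_lt(abs(sim_p - closed), 3 * sqrt(closed * (1 - closed) / 1e5))
  # monotone non-decreasing in delay
  pd <- vapply(c(0, 0.25, 0.5, 1), function(d)
    p_exit(truth_fit, 2, 0, delay = d, n_drivers = 4000, seed = 9)$mean,
    numeric(1))
  expect_true(all(diff(pd) >= 0))
  # threshold pushed to -Inf-wards kills the risk
  tiny <- p_exit(truth_fit, 2, 0, threshold = -5, n_drivers = 2000,
                 seed = 10)$mean
  expect_lt(tiny, 1e-6)
  expect_error(p_exit(truth_fit, 2, threshold = Inf), "finite")
})

test_that("risk curves are load-ordered, seeded, and flag extrapolation", {
  grid <- seq(1, 8, by = 0.5)
  c0 <- exit_risk_curve(truth_fit, grid, load = 0, n_drivers = 4000, seed = 11)
  c1 <- exit_risk_curve(truth_fit, grid, load = 1, n_drivers = 4000, seed = 11)
  expect_true(all(c1$p_exit >= c0$p_exit))
  expect_identical(c0$p_exit,
                   exit_risk_curve(truth_fit, grid, load = 0,
                                   n_drivers = 4000, seed = 11)$p_exit)
  expect_true(all(c0$extrapolated[grid < 2.23]))
  expect_false(any(c0$extrapolated[grid >= 2.23]))
  # steep fall near zero, then flattening (no guaranteed further decrease)
  expect_gt(c0$p_exit[1], 5 * c0$p_exit[grid == 4])
  # bands nest pointwise
  expect_true(all(c0$lo_95 <= c0$lo_68 & c0$hi_68 <= c0$hi_95))
})

test_that("predictive sampling reproduces the generator marginal", {
  # with the posterior collapsed to the generating truth, full-source
  # predictive draws and generator draws are one distribution
  pop <- population_params()
  p <- predictive_tlc(truth_fit, 6, 0, n_sim = 10000, seed = 12)
  set.seed(13)
  eff <- draw_participants(pop, 10000)
  ms <- trial_mu_sigma(eff, 6, 0)
  gen <- sample_tlc_t(ms$mu, ms$sigma, 6, -Inf)$tlc_t
  ks <- suppressWarnings(ks.test(p$samples, gen))
  expect_gt(ks$p.value, 0.01)
})

test_that("steering predictions scale as the fitted power law", {
  sfit <- point_posterior(population_params(sd_gamma = rep(0, 4)), "swa")
  pr <- predict(sfit, tlc_t = c(1, 2), load = 0, n_sim = 2000, seed = 14)
  expect_equal(pr$geom_mean[1], exp(3.57), tolerance = 1e-6)
  expect_equal(pr$geom_mean[2] / pr$geom_mean[1], 2^(-0.85), tolerance = 1e-6)
})
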