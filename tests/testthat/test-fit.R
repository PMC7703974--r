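# Sampler-level behaviour on small data; full-size recovery lives in
# test-acceptance.R.

test_that("a small hierarchical timing fit returns a well-formed posterior", {
  tr <- apply_exclusions(generate_study(design = small_design(), seed = 21))
  fit <- suppressWarnings(fit_tlc(tr$trials, control = quick_ctrl(seed = 1)))
  expect_s3_class(fit, "takeover_fit")
  dr <- as.matrix(fit)
  expect_equal(nrow(dr), 2 * 200)
  expect_true(all(c("beta0", "betaF", "betaL", "betaFL", "alpha0", "alphaF",
                    "alphaL", "sd_beta0", "sd_alphaL") %in% colnames(dr)))
  expect_true(all(dr[, grep("^sd_", colnames(dr))] >= 0))
  expect_true(is.finite(fit$diagnostics$max_rhat))
  s <- summary(fit)
  expect_true(all(s$lower <= s$mean & s$mean <= s$upper))
  # exponentiated twins are draw-wise transforms, not exp of the summary
  a0 <- dr[, "alpha0"]
  row <- s[s$parameter == "alpha0", ]
  expect_equal(row$exp_mean, mean(exp(a0)))
  expect_gt(row$exp_mean, exp(row$mean)) # Jensen gap
})

test_that("the no-load submodel drops the load coefficients", {
  tr <- apply_exclusions(generate_study(design = small_design(), seed = 22))
  tr0 <- tr$trials[tr$trials$load == 0, ]
  fit <- suppressWarnings(
    fit_tlc(tr0, control = quick_ctrl(seed = 2), load_terms = FALSE))
  dr <- as.matrix(fit)
  expect_false(any(c("betaL", "betaFL", "alphaL") %in% colnames(dr)))
  expect_true(all(c("beta0", "betaF", "alpha0", "alphaF") %in% colnames(dr)))
})

test_that("degenerate posterior summaries collapse to the point", {
  fit <- point_posterior(population_params(), "tlc")
  s <- summary(fit)
  expect_equal(s$mean[s$parameter == "beta0"], 0.33)
  expect_equal(s$lower, s$mean)
  expect_equal(s$upper, s$mean)
})

test_that("a flat steering fit matches the maximum-likelihood oracle", {
  # single participant, random effects disabled: the posterior under weak
  # priors should agree with plain least squares on the log scale
  set.seed(31)
  n <- 400
  tlc_t <- exp(runif(n, log(0.5), log(8)))
  load <- rep(0:1, each = n / 2)
  mu_ln <- 3.57 - 0.85 * log(tlc_t) - 0.13 * load + 0.01 * log(tlc_t) * load
  tr <- data.frame(participant_id = 1, load = load, tlc_f_s = 10,
                   onset_s = 6, tlc_end_s = 1, took_over = TRUE,
                   tlc_t_s = tlc_t, rt_s = 10 - tlc_t,
                   swa_max_deg = exp(rnorm(n, mu_ln, 0.35)),
                   excluded_pre_onset = FALSE, swa_invalid = FALSE)
  fit <- suppressWarnings(fit_swa(tr, control = quick_ctrl(seed = 3,
                                                  draws = 400),
                                  hierarchical = FALSE))
  ml <- lm(log(swa_max_deg) ~ log(tlc_t_s) * load, data = tr)
  b <- coef(fit)
  bo <- coef(ml)[c("(Intercept)", "log(tlc_t_s)", "load", "log(tlc_t_s):load")]
  ses <- summary(ml)$coefficients[, 2]
  expect_true(all(abs(b - bo) < 3 * ses))
})

test_that("with no data the posterior reproduces the prior", {
  empty <- generate_study(design = small_design(), seed = 1)[0, ]
  fit <- suppressWarnings(
    fit_tlc(empty, control = quick_ctrl(seed = 4, draws = 1500, chains = 2),
            hierarchical = FALSE))
  dr <- as.matrix(fit)
  # fixed effects have Normal(0, 2) priors
  expect_lt(abs(mean(dr[, "beta0"])), 0.25)
  expect_equal(sd(dr[, "betaF"]), 2, tolerance = 0.15)
  ks <- suppressWarnings(ks.test(dr[, "alpha0"], "pnorm", 0, 2))
  expect_gt(ks$p.value, 0.001)
})

test_that("convergence gate warns on hopelessly short chains", {
  tr <- apply_exclusions(generate_study(design = small_design(), seed = 23))
  expect_warning(
    fit_tlc(tr$trials, control = mcmc_control(chains = 2, adapt = 30,
                                              warmup = 10, draws = 30,
                                              seed = 5)),
    "convergence")
})

test_that("posterior draws round-trip through CSV", {
  tr <- apply_exclusions(generate_study(design = small_design(), seed = 24))
  fit <- suppressWarnings(
    fit_swa(tr$trials, control = quick_ctrl(seed = 6, draws = 50)))
  path <- tempfile(fileext = ".csv")
  write_draws(fit, path)
  back <- read.csv(path, check.names = FALSE)
  expect_equal(nrow(back), 2 * 50)
  expect_equal(back$gamma0, as.numeric(as.matrix(fit)[, "gamma0"]),
               tolerance = 1e-9)
  expect_true(file.exists(paste0(path, ".diag.json")))
})
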