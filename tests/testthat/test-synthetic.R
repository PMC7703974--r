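test_that("participant draws respect the population distribution", {
  pop0 <- population_params(sd_beta = rep(0, 4), sd_alpha = rep(0, 3),
                            sd_gamma = rep(0, 4))
  eff <- draw_participants(pop0, 5, seed = 1)
  expect_true(all(abs(eff$beta0 - 0.33) < 1e-12))
  expect_true(all(abs(eff$gammaT - (-0.85)) < 1e-12))

  eff1 <- draw_participants(population_params(), 10, seed = 42)
  eff2 <- draw_participants(population_params(), 10, seed = 42)
  expect_identical(eff1, eff2)

  # Monte-Carlo check of the between-participant SD (3 SEs at n = 1e5)
  big <- draw_participants(population_params(), 1e5, seed = 3)
  se <- 0.10 / sqrt(2 * (1e5 - 1))
  expect_lt(abs(sd(big$betaF) - 0.10), 3 * se)
  # and of a non-trivial correlation structure
  cb <- diag(4); cb[1, 2] <- cb[2, 1] <- 0.5
  bigc <- draw_participants(population_params(corr_beta = cb), 1e5, seed = 4)
  expect_lt(abs(cor(bigc$beta0, bigc$betaF) - 0.5), 0.01)
  expect_error(population_params(corr_beta = diag(4) * NA), "symmetric")
})

test_that("trial-level location and scale follow the submodels", {
  pop <- population_params()
  eff <- as.data.frame(as.list(c(pop$beta, pop$alpha, pop$gamma)))
  ms <- trial_mu_sigma(eff, tlc_f = 2, load = 0)
  expect_equal(ms$mu, 0.33 + 0.36 * 2)
  ms1 <- trial_mu_sigma(eff, tlc_f = 1, load = 0)
  expect_equal(ms1$sigma, exp(-2.47)) # about 0.08: 8% of TLC_F magnitude
  # multiplicative load effect on the spread
  r <- trial_mu_sigma(eff, 4, 1)$sigma / trial_mu_sigma(eff, 4, 0)$sigma
  expect_equal(r, exp(0.09))
  expect_error(trial_mu_sigma(eff, -1, 0), "tlc_f")
})

test_that("takeover sampling respects truncation and censoring", {
  # degenerate draw
  d <- sample_tlc_t(mu = 2, sigma = 0, tlc_f = 5, tlc_end = 1)
  expect_equal(d$tlc_t, 2)
  expect_true(d$took_over)
  # truncation respected for every draw
  d <- sample_tlc_t(rep(4, 1e5), 2, tlc_f = 5, tlc_end = -10, seed = 1)
  expect_true(all(d$tlc_t < 5))
  # moments match a rejection-sampling oracle within 3 MC SEs
  set.seed(2)
  raw <- rnorm(4e5, 4, 2)
  oracle <- raw[raw < 5][1:1e5]
  se_m <- sd(oracle) / sqrt(1e5)
  expect_lt(abs(mean(d$tlc_t) - mean(oracle)), 3 * sqrt(2) * se_m)
  expect_lt(abs(sd(d$tlc_t) - sd(oracle)), 3 * sqrt(2) * se_m)
  # censoring binds on the latent scale
  dc <- sample_tlc_t(rep(1, 1e4), 0.5, tlc_f = 3, tlc_end = 1, seed = 3)
  expect_true(any(!dc$took_over))
  expect_true(all(is.na(dc$tlc_t[!dc$took_over])))
  expect_true(all(dc$tlc_t[dc$took_over] >= 1))
})

test_that("steering corrections follow the lognormal power law", {
  pop <- population_params()
  eff <- as.data.frame(as.list(c(pop$beta, pop$alpha, pop$gamma)))
  s <- sample_swa_max(eff, tlc_t = rep(1, 2e5), load = 0, seed = 1)
  gm <- exp(mean(log(s)))
  se <- 0.35 / sqrt(2e5)
  expect_lt(abs(log(gm) - 3.57), 3 * se) # geometric mean about 35.67 deg
  # power law: doubling T multiplies the geometric mean by 2^gammaT
  s2 <- sample_swa_max(eff, tlc_t = rep(2, 2e5), load = 0, seed = 2)
  expect_equal(exp(mean(log(s2)) - mean(log(s))), 2^(-0.85), tolerance = 0.01)
  # load multiplies the geometric mean by e^gammaL (about a 12% reduction)
  sl <- sample_swa_max(eff, tlc_t = rep(1, 2e5), load = 1, seed = 3)
  expect_equal(exp(mean(log(sl)) - mean(log(s))), exp(-0.13), tolerance = 0.01)
  expect_error(sample_swa_max(eff, tlc_t = 0, load = 0), "tlc_t")
})

test_that("generated studies have the designed structure", {
  des <- study_design(n_participants = 2)
  tr <- generate_study(design = des, seed = 11)
  expect_equal(nrow(tr), 2 * 192)
  expect_equal(as.integer(table(tr$participant_id)), c(192L, 192L))
  # six repetitions of each Repeated condition per load and direction
  rep1 <- tr[tr$participant_id == 1 & tr$repeated & tr$load == 0 &
               tr$direction == "left", ]
  expect_equal(as.integer(table(rep1$condition_id)), rep(6L, 4))
  expect_equal(length(unique(tr$condition_id)), 28)
  # truncation invariant holds everywhere
  obs <- tr[tr$took_over, ]
  expect_true(all(obs$tlc_t_s < obs$tlc_f_s))
  expect_true(all(obs$rt_s > 0))
  # censored trials carry no takeover time
  expect_true(all(is.na(tr$tlc_t_s[!tr$took_over])))
  # bit-reproducible per seed
  expect_identical(tr, generate_study(design = des, seed = 11))
})

test_that("noise-free responses recover the structural reaction-time slope", {
  tr <- generate_study(design = study_design(n_participants = 1), seed = 1,
                       noise_free = TRUE)
  tr0 <- tr[tr$load == 0 & tr$took_over, ]
  fitlm <- lm(rt_s ~ tlc_f_s, data = tr0)
  expect_equal(unname(coef(fitlm)[2]), 1 - 0.36, tolerance = 1e-8)
})

test_that("censoring probability grows as the observation window shrinks", {
  pop <- population_params()
  des <- study_design(n_participants = 6)
  tr <- generate_study(pop, des, seed = 5)
  gap <- tr$tlc_f_s - tr$tlc_end_s  # observation window length
  cens_rate_small <- mean(!tr$took_over[gap < quantile(gap, 0.33)])
  cens_rate_large <- mean(!tr$took_over[gap > quantile(gap, 0.67)])
  expect_gt(cens_rate_small, cens_rate_large)
})

test_that("exclusion rules drop and flag the right trials", {
  tr <- generate_study(design = study_design(n_participants = 2), seed = 9)
  # manufacture a pre-onset takeover and a last-instant takeover
  tr$rt_s[1] <- -0.3
  tr$rt_s[2] <- 15 - tr$onset_s[2] - 0.1 # takeover 0.1 s before trial end
  tr$took_over[2] <- TRUE
  tr$swa_max_deg[2] <- 10
  res <- apply_exclusions(tr)
  expect_equal(res$report$n_pre_onset, 1)
  expect_false(1 %in% as.integer(rownames(res$trials)))
  kept2 <- res$trials[as.integer(rownames(res$trials)) == 2, ]
  expect_true(kept2$swa_invalid)
  expect_true(is.na(kept2$swa_max_deg))
  # a clean dataset passes through unchanged
  clean <- generate_study(design = study_design(n_participants = 1), seed = 2)
  res2 <- apply_exclusions(clean)
  expect_equal(res2$report$n_pre_onset, 0)
  expect_equal(nrow(res2$trials), nrow(clean))
})
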