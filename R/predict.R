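# Posterior-predictive machinery: predictive intervals for unseen drivers,
# variance decomposition, and road-departure risk curves.

#' Degenerate posterior at fixed population parameters
#'
#' Wraps a [population_params()] object as a `"takeover_fit"` whose posterior
#' is a point mass, so the posterior-predictive machinery can be driven from
#' published point estimates when no fitted posterior is available. Because
#' random-effect correlations are not part of the published summaries, they
#' are taken as zero; outputs are approximate in that respect.
#'
#' @param pop A [population_params()] object.
#' @param model `"tlc"` or `"swa"`.
#' @param draws Number of (identical) draws to materialise (default 1000).
#' @return A `"takeover_fit"` with a degenerate posterior.
#' @export
point_posterior <- function(pop, model = c("tlc", "swa"), draws = 1000) {
  model <- match.arg(model)
  stopifnot(inherits(pop, "population_params"))
  if (model == "tlc") {
    vals <- c(pop$beta, pop$alpha,
              stats::setNames(c(pop$sd_beta, pop$sd_alpha),
                              paste0("sd_", c(names(pop$beta), names(pop$alpha)))))
    nm <- tlc_par_names(TRUE, TRUE)
  } else {
    vals <- c(pop$gamma,
              stats::setNames(pop$sd_gamma, paste0("sd_", names(pop$gamma))),
              sigma = pop$sigma_swa)
    nm <- swa_par_names(TRUE, TRUE)
  }
  m <- matrix(vals, nrow = draws, ncol = length(vals), byrow = TRUE,
              dimnames = list(NULL, names(vals)))
  samples <- coda::mcmc.list(coda::mcmc(m))
  diag <- list(rhat = stats::setNames(rep(NA_real_, length(vals)), names(vals)),
               ess = stats::setNames(rep(Inf, length(vals)), names(vals)),
               max_rhat = NA_real_, min_ess = Inf)
  info <- list(n_obs = 0L, n_censored = 0L, n_participants = 0L,
               pid_levels = integer(), load_terms = TRUE, hierarchical = TRUE,
               point_mass = TRUE)
  structure(list(model = model, samples = samples, pars = nm,
                 diagnostics = diag, converged = TRUE, data_info = info,
                 priors = NULL, control = NULL, call = match.call()),
            class = "takeover_fit")
}

# Extract fixed-effect and SD draw matrices for the TLC model, padding the
# load terms with zeros when the fit excluded them.
tlc_draw_blocks <- function(fit) {
  dr <- as.matrix(fit)
  n <- nrow(dr)
  zero <- numeric(n)
  pick <- function(p) if (p %in% colnames(dr)) dr[, p] else zero
  list(beta = cbind(pick("beta0"), pick("betaF"), pick("betaL"), pick("betaFL")),
       alpha = cbind(pick("alpha0"), pick("alphaF"), pick("alphaL")),
       sd_beta = cbind(pick("sd_beta0"), pick("sd_betaF"), pick("sd_betaL"),
                       pick("sd_betaFL")),
       sd_alpha = cbind(pick("sd_alpha0"), pick("sd_alphaF"), pick("sd_alphaL")))
}

# Column-wise posterior medians of the blocks.
block_medians <- function(blocks)
  lapply(blocks, function(m) apply(m, 2, stats::median))

# Per-simulation driver-level (mu, sigma) for one condition.
# theta: list of beta (n x 4), alpha (n x 3) matrices already including any
# driver-level deviations.
condition_mu_sigma <- function(theta, tlc_f, load) {
  mu <- theta$beta[, 1] + theta$beta[, 2] * tlc_f + theta$beta[, 3] * load +
    theta$beta[, 4] * tlc_f * load
  sigma <- exp(theta$alpha[, 1] + theta$alpha[, 2] * log(tlc_f) +
                 theta$alpha[, 3] * load)
  list(mu = mu, sigma = sigma)
}

# Assemble n_sim driver-level parameter draws from a fit, honouring the
# requested uncertainty sources. Common random numbers: the standard-normal
# driver deviates `z` are reused across source subsets when supplied.
driver_parameters <- function(fit, n_sim, sources, z = NULL, draw_idx = NULL) {
  blocks <- tlc_draw_blocks(fit)
  if ("estimation" %in% sources) {
    if (is.null(draw_idx))
      draw_idx <- sample.int(nrow(blocks$beta), n_sim, replace = TRUE)
    beta <- blocks$beta[draw_idx, , drop = FALSE]
    alpha <- blocks$alpha[draw_idx, , drop = FALSE]
    sdb <- blocks$sd_beta[draw_idx, , drop = FALSE]
    sda <- blocks$sd_alpha[draw_idx, , drop = FALSE]
  } else {
    med <- block_medians(blocks)
    beta <- matrix(med$beta, n_sim, 4, byrow = TRUE)
    alpha <- matrix(med$alpha, n_sim, 3, byrow = TRUE)
    sdb <- matrix(med$sd_beta, n_sim, 4, byrow = TRUE)
    sda <- matrix(med$sd_alpha, n_sim, 3, byrow = TRUE)
  }
  if ("between" %in% sources) {
    if (is.null(z)) z <- matrix(stats::rnorm(n_sim * 7), n_sim, 7)
    beta <- beta + z[, 1:4] * sdb
    alpha <- alpha + z[, 5:7] * sda
  }
  list(beta = beta, alpha = alpha)
}

#' Posterior-predictive takeover criticality for new drivers
#'
#' Nested posterior-predictive simulation for a single condition: optionally
#' draw population parameters from the posterior (`"estimation"`; otherwise
#' posterior medians are used), optionally draw a new driver's coefficients
#' from the random-effect distribution (`"between"`), and optionally draw a
#' single trial outcome from the driver's truncated normal (`"within"`;
#' otherwise the driver mean is returned). With all three sources the samples
#' describe single future trials by unseen drivers.
#'
#' @param fit A `"takeover_fit"` for the timing model (or [point_posterior()]).
#' @param tlc_f Failure criticality in seconds.
#' @param load Load indicator, 0 or 1.
#' @param sources Character subset of
#'   `c("within", "between", "estimation")`.
#' @param n_sim Number of simulations (default 10000).
#' @param seed Optional integer seed.
#' @return A list of class `"predictive_tlc"`: `samples`, and `summary` (a
#'   one-row data frame with mean, SD, and 68.3%/95.5% central intervals).
#' @export
predictive_tlc <- function(fit, tlc_f, load = 0,
                           sources = c("within", "between", "estimation"),
                           n_sim = 10000, seed = NULL) {
  stopifnot(inherits(fit, "takeover_fit"), fit$model == "tlc")
  if (length(sources))
    sources <- match.arg(sources, c("within", "between", "estimation"),
                         several.ok = TRUE)
  if (!is.null(seed)) set.seed(seed)
  th <- driver_parameters(fit, n_sim, sources)
  ms <- condition_mu_sigma(th, tlc_f, load)
  if ("within" %in% sources) {
    u <- stats::runif(n_sim)
    samples <- ms$mu + ms$sigma *
      qtrunc_upper(u, (tlc_f - ms$mu) / ms$sigma)
  } else samples <- ms$mu
  s <- summarise_predictive(samples, tlc_f, load)
  structure(list(samples = samples, summary = s), class = "predictive_tlc")
}

summarise_predictive <- function(samples, tlc_f, load) {
  q <- stats::quantile(samples, c(0.02275, 0.15865, 0.84135, 0.97725),
                       names = FALSE)
  data.frame(tlc_f = tlc_f, load = load, mean = mean(samples),
             sd = stats::sd(samples), lo_68 = q[2], hi_68 = q[3],
             lo_95 = q[1], hi_95 = q[4])
}

#' Decompose predictive variability into its sources
#'
#' Sequential attribution of the predictive coefficient of variation
#' (CV = predictive SD / predictive mean) into within-participant
#' variability, between-participant variability, and estimation uncertainty:
#' the within component is the CV with trial noise only (posterior-median
#' parameters, no driver variation), the between component is the increase
#' when new-driver variation is added, and the estimation component is the
#' further increase when parameters are drawn from the posterior. Components
#' sum to the total CV by construction. Common random numbers are shared
#' across the three nested simulations so the differences are not dominated
#' by Monte Carlo noise.
#'
#' @param fit A `"takeover_fit"` for the timing model.
#' @param conditions Data frame with columns `tlc_f` and `load` over which
#'   the CV contributions are averaged (default: criticalities 3 to 15 s in
#'   steps of 2, for each load).
#' @param n_sim Simulations per condition (default 10000).
#' @param seed Optional integer seed.
#' @return A data frame of class `"cv_decomposition"`, one row per load:
#'   `within`, `between`, `estimation`, `total`.
#' @export
cv_decompose <- function(fit, conditions = NULL, n_sim = 10000, seed = NULL) {
  stopifnot(inherits(fit, "takeover_fit"), fit$model == "tlc")
  if (is.null(conditions))
    conditions <- expand.grid(tlc_f = seq(3, 15, by = 2), load = c(0, 1))
  if (!is.null(seed)) set.seed(seed)

  z <- matrix(stats::rnorm(n_sim * 7), n_sim, 7)
  u <- stats::runif(n_sim)
  blocks <- tlc_draw_blocks(fit)
  draw_idx <- sample.int(nrow(blocks$beta), n_sim, replace = TRUE)

  cv_one <- function(tlc_f, load, sources) {
    th <- driver_parameters(fit, n_sim, sources, z = z, draw_idx = draw_idx)
    ms <- condition_mu_sigma(th, tlc_f, load)
    x <- ms$mu + ms$sigma * qtrunc_upper(u, (tlc_f - ms$mu) / ms$sigma)
    stats::sd(x) / mean(x)
  }

  out <- lapply(split(conditions, conditions$load), function(cc) {
    cvs <- t(vapply(seq_len(nrow(cc)), function(i) {
      w <- cv_one(cc$tlc_f[i], cc$load[i], "within")
      wb <- cv_one(cc$tlc_f[i], cc$load[i], c("within", "between"))
      all3 <- cv_one(cc$tlc_f[i], cc$load[i],
                     c("within", "between", "estimation"))
      c(w, wb, all3)
    }, numeric(3)))
    m <- colMeans(cvs)
    data.frame(load = cc$load[1], within = m[1], between = m[2] - m[1],
               estimation = m[3] - m[2], total = m[3])
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  class(out) <- c("cv_decomposition", "data.frame")
  out
}

#' @export
print.cv_decomposition <- function(x, digits = 3, ...) {
  cat("Predictive CV decomposition (within + between + estimation = total)\n")
  df <- as.data.frame(x)
  df[-1] <- lapply(df[-1], round, digits)
  print(df, row.names = FALSE)
  invisible(x)
}

# Driver-level P(Exit) values for one condition: the truncated-normal
# probability mass below (threshold + delay), per simulated driver.
driver_exit_probs <- function(fit, tlc_f, load, threshold, delay, n_drivers,
                              z = NULL, draw_idx = NULL) {
  th <- driver_parameters(fit, n_drivers,
                          c("between", "estimation"), z = z,
                          draw_idx = draw_idx)
  ms <- condition_mu_sigma(th, tlc_f, load)
  cut <- threshold + delay
  num <- stats::pnorm((cut - ms$mu) / ms$sigma)
  den <- stats::pnorm((tlc_f - ms$mu) / ms$sigma)
  p <- if (cut >= tlc_f) rep(1, length(num)) else pmin(num / den, 1)
  p[den <= 0] <- 1
  p
}

#' Probability of exiting the road before takeover
#'
#' For each simulated driver (a draw of participant-level coefficients from
#' the posterior and its random-effect distribution), the probability that a
#' failure of criticality `tlc_f` ends with a takeover criticality below the
#' safety threshold — i.e. the truncated-normal probability mass below
#' `threshold + delay`. The population value is the mean over drivers;
#' driver-quantile bands convey between-driver spread.
#'
#' @param fit A `"takeover_fit"` for the timing model (or [point_posterior()]).
#' @param tlc_f Failure criticality in seconds.
#' @param load Load indicator, 0 or 1.
#' @param threshold Safety threshold in seconds (default 0.5): takeovers with
#'   less remaining margin than this are counted as road exits.
#' @param delay Additional response delay in seconds (default 0), applied by
#'   shifting the threshold (equivalent to delaying every response).
#' @param n_drivers Number of simulated drivers (default 10000).
#' @param seed Optional integer seed.
#' @return A list of class `"p_exit"`: `mean`, `bands` (68.3/95.5% driver
#'   quantiles), and the per-driver probabilities `drivers`.
#' @export
p_exit <- function(fit, tlc_f, load = 0, threshold = 0.5, delay = 0,
                   n_drivers = 10000, seed = NULL) {
  stopifnot(inherits(fit, "takeover_fit"), fit$model == "tlc")
  if (!is.finite(threshold)) stop("`threshold` must be finite")
  if (!is.null(seed)) set.seed(seed)
  p <- driver_exit_probs(fit, tlc_f, load, threshold, delay, n_drivers)
  q <- stats::quantile(p, c(0.02275, 0.15865, 0.84135, 0.97725), names = FALSE)
  structure(list(mean = mean(p),
                 bands = data.frame(lo_68 = q[2], hi_68 = q[3],
                                    lo_95 = q[1], hi_95 = q[4]),
                 drivers = p,
                 tlc_f = tlc_f, load = load, threshold = threshold,
                 delay = delay),
            class = "p_exit")
}

#' @export
print.p_exit <- function(x, ...) {
  cat(sprintf(paste0("P(Exit) at TLC_F = %.2f s (load %d, threshold %.2f s,",
                     " delay %.2f s):\n  mean %.3f%%, 68.3%% band [%.3f, %.3f]%%,",
                     " 95.5%% band [%.3f, %.3f]%%\n"),
              x$tlc_f, x$load, x$threshold, x$delay, 100 * x$mean,
              100 * x$bands$lo_68, 100 * x$bands$hi_68,
              100 * x$bands$lo_95, 100 * x$bands$hi_95))
  invisible(x)
}

#' Road-departure risk curve
#'
#' [p_exit()] evaluated over a grid of failure criticalities with a shared
#' driver sample (so the curve is smooth in the grid). Grid points outside
#' the fitted criticality range are flagged as extrapolation.
#'
#' @param fit A `"takeover_fit"` for the timing model.
#' @param tlc_f Grid of failure criticalities in seconds.
#' @param load Load indicator, 0 or 1.
#' @param threshold,delay As in [p_exit()].
#' @param n_drivers Number of simulated drivers shared across the grid.
#' @param seed Optional integer seed.
#' @param support Fitted criticality range used to flag extrapolation
#'   (default 2.23 to 19.51 s, or the fitted data range when available).
#' @return A data frame of class `"exit_risk_curve"`: `tlc_f`, `load`,
#'   `threshold`, `delay`, `p_exit`, band columns, `extrapolated`.
#' @export
exit_risk_curve <- function(fit, tlc_f = seq(0.5, 12, by = 0.25), load = 0,
                            threshold = 0.5, delay = 0, n_drivers = 10000,
                            seed = NULL, support = NULL) {
  stopifnot(inherits(fit, "takeover_fit"), fit$model == "tlc")
  if (!is.null(seed)) set.seed(seed)
  if (is.null(support))
    support <- if (!is.null(fit$data_info$tlc_f_range))
      fit$data_info$tlc_f_range else c(2.23, 19.51)
  z <- matrix(stats::rnorm(n_drivers * 7), n_drivers, 7)
  blocks <- tlc_draw_blocks(fit)
  draw_idx <- sample.int(nrow(blocks$beta), n_drivers, replace = TRUE)
  rows <- lapply(tlc_f, function(f) {
    p <- driver_exit_probs(fit, f, load, threshold, delay, n_drivers,
                           z = z, draw_idx = draw_idx)
    q <- stats::quantile(p, c(0.02275, 0.15865, 0.84135, 0.97725),
                         names = FALSE)
    data.frame(tlc_f = f, load = load, threshold = threshold, delay = delay,
               p_exit = mean(p), lo_68 = q[2], hi_68 = q[3], lo_95 = q[1],
               hi_95 = q[4], extrapolated = f < support[1] | f > support[2])
  })
  out <- do.call(rbind, rows)
  class(out) <- c("exit_risk_curve", "data.frame")
  out
}

#' @export
plot.exit_risk_curve <- function(x, add = FALSE, col = "steelblue",
                                 main = "Road-departure risk", ...) {
  if (!add) {
    graphics::plot(x$tlc_f, 100 * x$p_exit, type = "n",
                   xlab = expression(TLC[F] ~ "(s)"),
                   ylab = "P(Exit) (%)", main = main, ...)
  }
  graphics::polygon(c(x$tlc_f, rev(x$tlc_f)),
                    100 * c(x$lo_95, rev(x$hi_95)),
                    col = grDevices::adjustcolor(col, 0.15), border = NA)
  graphics::polygon(c(x$tlc_f, rev(x$tlc_f)),
                    100 * c(x$lo_68, rev(x$hi_68)),
                    col = grDevices::adjustcolor(col, 0.3), border = NA)
  graphics::lines(x$tlc_f, 100 * x$p_exit, col = col, lwd = 2)
  invisible(x)
}

#' Posterior predictions from a fitted model
#'
#' For the timing model, returns the predictive summary over a grid of
#' failure criticalities (see [predictive_tlc()]). For the steering model,
#' returns the geometric-mean curve of `SWA_Max` over a grid of takeover
#' criticalities, with predictive quantiles from the lognormal draws.
#'
#' @param object A `"takeover_fit"`.
#' @param tlc_f Criticality grid in seconds (timing model).
#' @param tlc_t Takeover-criticality grid in seconds (steering model).
#' @param load Load indicator, 0 or 1.
#' @param sources Uncertainty sources (timing model; see [predictive_tlc()]).
#' @param n_sim Simulations per grid point.
#' @param seed Optional integer seed.
#' @param ... Unused.
#' @return A data frame with one row per grid point.
#' @export
predict.takeover_fit <- function(object, tlc_f = seq(2.5, 19.5, by = 0.5),
                                 tlc_t = seq(0.5, 8, by = 0.25), load = 0,
                                 sources = c("within", "between", "estimation"),
                                 n_sim = 4000, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  if (object$model == "tlc") {
    out <- do.call(rbind, lapply(tlc_f, function(f)
      predictive_tlc(object, f, load, sources, n_sim)$summary))
    return(out)
  }
  dr <- as.matrix(object)
  zero <- numeric(nrow(dr))
  pick <- function(p) if (p %in% colnames(dr)) dr[, p] else zero
  g <- cbind(pick("gamma0"), pick("gammaT"), pick("gammaL"), pick("gammaTL"))
  sdg <- cbind(pick("sd_gamma0"), pick("sd_gammaT"), pick("sd_gammaL"),
               pick("sd_gammaTL"))
  sig <- dr[, "sigma"]
  idx <- sample.int(nrow(dr), n_sim, replace = TRUE)
  z <- matrix(stats::rnorm(n_sim * 4), n_sim, 4)
  gi <- g[idx, , drop = FALSE] + z * sdg[idx, , drop = FALSE]
  eps <- stats::rnorm(n_sim, 0, sig[idx])
  out <- lapply(tlc_t, function(tt) {
    mu_ln <- gi[, 1] + gi[, 2] * log(tt) + gi[, 3] * load +
      gi[, 4] * log(tt) * load
    s <- exp(mu_ln + eps)
    q <- stats::quantile(s, c(0.02275, 0.15865, 0.84135, 0.97725),
                         names = FALSE)
    data.frame(tlc_t = tt, load = load, geom_mean = exp(mean(mu_ln)),
               lo_68 = q[2], hi_68 = q[3], lo_95 = q[1], hi_95 = q[4])
  })
  do.call(rbind, out)
}

#' Simulate takeover responses from the fitted model
#'
#' Posterior-predictive replication of a trial table: participant-level
#' coefficients are drawn per simulation from a random posterior draw, and
#' responses are re-sampled from the truncated/censored (timing model) or
#' lognormal (steering model) observation model at the fitted trials'
#' conditions.
#'
#' @param object A `"takeover_fit"`.
#' @param nsim Number of replicated tables (default 1).
#' @param seed Optional integer seed.
#' @param trials The trial table whose conditions are replicated.
#' @param ... Unused.
#' @return A list of `nsim` trial tables.
#' @export
simulate.takeover_fit <- function(object, nsim = 1, seed = NULL, trials, ...) {
  if (!is.null(seed)) set.seed(seed)
  dr <- as.matrix(object)
  n <- nrow(trials)
  out <- vector("list", nsim)
  for (s in seq_len(nsim)) {
    i <- sample.int(nrow(dr), 1L)
    row <- dr[i, ]
    pick <- function(p) if (p %in% names(row)) row[[p]] else 0
    tr <- trials
    if (object$model == "tlc") {
      pid <- match(trials$participant_id, object$data_info$pid_levels)
      eff <- data.frame(
        beta0 = dr[i, sprintf("bj[%d,1]", pid)],
        betaF = dr[i, sprintf("bj[%d,2]", pid)],
        betaL = if ("betaL" %in% colnames(dr))
          dr[i, sprintf("bj[%d,3]", pid)] else 0,
        betaFL = if ("betaFL" %in% colnames(dr))
          dr[i, sprintf("bj[%d,4]", pid)] else 0,
        alpha0 = dr[i, sprintf("aj[%d,1]", pid)],
        alphaF = dr[i, sprintf("aj[%d,2]", pid)],
        alphaL = if ("alphaL" %in% colnames(dr))
          dr[i, sprintf("aj[%d,3]", pid)] else 0)
      ms <- trial_mu_sigma(eff, trials$tlc_f_s, trials$load)
      resp <- sample_tlc_t(ms$mu, ms$sigma, trials$tlc_f_s, trials$tlc_end_s)
      tr$tlc_t_s <- resp$tlc_t
      tr$took_over <- resp$took_over
      tr$rt_s <- trials$tlc_f_s - resp$tlc_t
    } else {
      pid <- match(trials$participant_id, object$data_info$pid_levels)
      eff <- data.frame(
        gamma0 = dr[i, sprintf("gj[%d,1]", pid)],
        gammaT = dr[i, sprintf("gj[%d,2]", pid)],
        gammaL = if ("gammaL" %in% colnames(dr))
          dr[i, sprintf("gj[%d,3]", pid)] else 0,
        gammaTL = if ("gammaTL" %in% colnames(dr))
          dr[i, sprintf("gj[%d,4]", pid)] else 0)
      ok <- tr$took_over & !is.na(tr$tlc_t_s) & tr$tlc_t_s > 0
      tr$swa_max_deg <- NA_real_
      tr$swa_max_deg[ok] <- sample_swa_max(eff[ok, ], tr$tlc_t_s[ok],
                                           tr$load[ok], pick("sigma"))
    }
    out[[s]] <- tr
  }
  out
}

#' Predictive-interval plot of a fitted model
#'
#' Timing model: predicted mean takeover criticality with 68.3% and 95.5%
#' predictive bands against failure criticality. Steering model: geometric
#' mean and predictive bands of the steering correction against takeover
#' criticality, drawn in log-log coordinates.
#'
#' @param x A `"takeover_fit"`.
#' @param load Load indicator, 0 or 1.
#' @param n_sim Simulations per grid point.
#' @param seed Optional seed.
#' @param col Band colour.
#' @param ... Passed to the underlying grid predictor.
#' @export
plot.takeover_fit <- function(x, load = 0, n_sim = 4000, seed = 1,
                              col = "grey40", ...) {
  pr <- predict(x, load = load, n_sim = n_sim, seed = seed, ...)
  if (x$model == "tlc") {
    graphics::plot(pr$tlc_f, pr$mean, type = "n",
                   ylim = range(pr$lo_95, pr$hi_95),
                   xlab = expression(TLC[F] ~ "(s)"),
                   ylab = expression(TLC[T] ~ "(s)"),
                   main = "Predicted takeover criticality")
    graphics::polygon(c(pr$tlc_f, rev(pr$tlc_f)), c(pr$lo_95, rev(pr$hi_95)),
                      col = grDevices::adjustcolor(col, 0.15), border = NA)
    graphics::polygon(c(pr$tlc_f, rev(pr$tlc_f)), c(pr$lo_68, rev(pr$hi_68)),
                      col = grDevices::adjustcolor(col, 0.3), border = NA)
    graphics::lines(pr$tlc_f, pr$mean, lwd = 2, col = col)
    graphics::abline(0, 1, lty = 2, col = "grey70")
  } else {
    graphics::plot(pr$tlc_t, pr$geom_mean, type = "n", log = "xy",
                   ylim = range(pr$lo_95, pr$hi_95),
                   xlab = expression(TLC[T] ~ "(s)"),
                   ylab = expression(SWA[Max] ~ "(deg)"),
                   main = "Predicted steering correction")
    graphics::polygon(c(pr$tlc_t, rev(pr$tlc_t)), c(pr$lo_95, rev(pr$hi_95)),
                      col = grDevices::adjustcolor(col, 0.15), border = NA)
    graphics::polygon(c(pr$tlc_t, rev(pr$tlc_t)), c(pr$lo_68, rev(pr$hi_68)),
                      col = grDevices::adjustcolor(col, 0.3), border = NA)
    graphics::lines(pr$tlc_t, pr$geom_mean, lwd = 2, col = col)
  }
  invisible(pr)
}
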