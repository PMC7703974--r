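# Generative population parameters and participant-level effects.

#' Population parameters of the takeover models
#'
#' All generative coefficients of the two distributional models, plus the
#' between-participant SDs and correlation matrices of their random effects.
#'
#' The takeover-timing model describes the criticality adopted at takeover,
#' `TLC_T`, as a normal distribution truncated above at the failure
#' criticality `F = TLC_F` and censored below at the trial-end threshold
#' `TLC_End`:
#' \deqn{\mu = \beta_0 + \beta_F F + \beta_L L + \beta_{FL} F L}
#' \deqn{\sigma = e^{\alpha_0} F^{\alpha_F} e^{\alpha_L L}}
#' where `L` is the cognitive-load indicator (1 = auditory memory task
#' present). The steering model describes the maximum steering correction
#' `SWA_Max` (degrees) as lognormal with a power-law dependence on the
#' criticality at takeover `T = TLC_T`:
#' \deqn{\ln SWA_{Max} \sim N(\gamma_0 + \gamma_T \ln T + \gamma_L L +
#'   \gamma_{TL} \ln T \, L,\; \sigma_{SWA})}
#'
#' Defaults are the published posterior means of the fitted models
#' (coefficients and random-effect SDs). Random-effect correlations were not
#' published; they default to identity matrices and are configurable for
#' sensitivity analyses. The residual SD of the steering model was likewise
#' not published; the default 0.35 (log scale) is this package's assumption
#' and is configurable.
#'
#' @param beta Length-4 vector `(beta0, betaF, betaL, betaFL)`, seconds scale.
#' @param alpha Length-3 vector `(alpha0, alphaF, alphaL)` on the log-sigma
#'   scale.
#' @param gamma Length-4 vector `(gamma0, gammaT, gammaL, gammaTL)` on the
#'   log-degrees scale.
#' @param sd_beta,sd_alpha,sd_gamma Non-negative between-participant SDs for
#'   each coefficient block.
#' @param corr_beta,corr_alpha,corr_gamma Correlation matrices for the blocks
#'   (symmetric, unit diagonal, positive semi-definite). Default identity.
#' @param sigma_swa Residual SD of `ln(SWA_Max)` (default 0.35).
#' @return An object of class `"population_params"`.
#' @export
#' @examples
#' pop <- population_params()
#' exp(pop$alpha[1]) # within-participant noise scale, about 8% of TLC_F
population_params <- function(beta = c(beta0 = 0.33, betaF = 0.36,
                                       betaL = -0.10, betaFL = -0.01),
                              alpha = c(alpha0 = -2.47, alphaF = 0.96,
                                        alphaL = 0.09),
                              gamma = c(gamma0 = 3.57, gammaT = -0.85,
                                        gammaL = -0.13, gammaTL = 0.01),
                              sd_beta = c(0.17, 0.10, 0.11, 0.07),
                              sd_alpha = c(0.33, 0.21, 0.14),
                              sd_gamma = c(0.18, 0.17, 0.14, 0.10),
                              corr_beta = diag(4), corr_alpha = diag(3),
                              corr_gamma = diag(4), sigma_swa = 0.35) {
  stopifnot(length(beta) == 4, length(alpha) == 3, length(gamma) == 4,
            length(sd_beta) == 4, length(sd_alpha) == 3, length(sd_gamma) == 4)
  if (any(c(sd_beta, sd_alpha, sd_gamma) < 0))
    stop("random-effect SDs must be >= 0")
  if (sigma_swa < 0) stop("`sigma_swa` must be >= 0")
  for (nm in c("corr_beta", "corr_alpha", "corr_gamma")) {
    m <- get(nm)
    if (anyNA(m) || !isSymmetric(unname(m)) || any(abs(diag(m) - 1) > 1e-12))
      stop(sprintf("`%s` must be symmetric with unit diagonal", nm))
    if (min(eigen(m, symmetric = TRUE, only.values = TRUE)$values) < -1e-8)
      stop(sprintf("`%s` must be positive semi-definite", nm))
  }
  structure(list(beta = stats::setNames(as.numeric(beta),
                                        c("beta0", "betaF", "betaL", "betaFL")),
                 alpha = stats::setNames(as.numeric(alpha),
                                         c("alpha0", "alphaF", "alphaL")),
                 gamma = stats::setNames(as.numeric(gamma),
                                         c("gamma0", "gammaT", "gammaL", "gammaTL")),
                 sd_beta = as.numeric(sd_beta), sd_alpha = as.numeric(sd_alpha),
                 sd_gamma = as.numeric(sd_gamma),
                 corr_beta = corr_beta, corr_alpha = corr_alpha,
                 corr_gamma = corr_gamma, sigma_swa = sigma_swa),
            class = "population_params")
}

#' @export
print.population_params <- function(x, ...) {
  cat("Population parameters\n")
  cat("  mu submodel (s):     ", paste(sprintf("%s=%.3g", names(x$beta), x$beta),
                                       collapse = ", "), "\n")
  cat("  ln-sigma submodel:   ", paste(sprintf("%s=%.3g", names(x$alpha), x$alpha),
                                       collapse = ", "), "\n")
  cat("  ln(SWA_Max) submodel:", paste(sprintf("%s=%.3g", names(x$gamma), x$gamma),
                                       collapse = ", "), "\n")
  cat("  sigma_swa =", x$sigma_swa, "(log scale)\n")
  invisible(x)
}

# One multivariate-normal block draw: n x k matrix centred on `centre` with
# SDs `sds` and correlation `corr`.
draw_block <- function(n, centre, sds, corr) {
  k <- length(centre)
  ch <- tryCatch(chol(corr),
                 error = function(e) stop("correlation matrix is not positive definite",
                                          call. = FALSE))
  z <- matrix(stats::rnorm(n * k), n, k) %*% ch
  sweep(z, 2, sds, `*`) + matrix(centre, n, k, byrow = TRUE)
}

#' Draw participant-level coefficients
#'
#' Draws each participant's coefficient blocks from multivariate normal
#' distributions centred on the population fixed effects, with the population
#' SDs and correlations.
#'
#' @param pop A [population_params()] object.
#' @param n Number of participants.
#' @param seed Optional integer seed (deterministic per seed).
#' @return A data frame with one row per participant: `participant_id`,
#'   `beta0 ... betaFL`, `alpha0 ... alphaL`, `gamma0 ... gammaTL`.
#' @export
draw_participants <- function(pop, n, seed = NULL) {
  stopifnot(inherits(pop, "population_params"))
  if (n <= 0) stop("`n` must be > 0")
  if (!is.null(seed)) set.seed(seed)
  b <- draw_block(n, pop$beta, pop$sd_beta, pop$corr_beta)
  a <- draw_block(n, pop$alpha, pop$sd_alpha, pop$corr_alpha)
  g <- draw_block(n, pop$gamma, pop$sd_gamma, pop$corr_gamma)
  out <- data.frame(participant_id = seq_len(n), b, a, g)
  names(out) <- c("participant_id", names(pop$beta), names(pop$alpha),
                  names(pop$gamma))
  out
}

#' Trial-level mean and spread of takeover criticality
#'
#' Evaluates the location-scale submodels for given participant coefficients:
#' `mu = beta0 + betaF*F + betaL*L + betaFL*F*L` and
#' `sigma = exp(alpha0) * F^alphaF * exp(alphaL*L)`.
#'
#' @param effects A data frame of participant coefficients (as returned by
#'   [draw_participants()]), recycled row-wise against `tlc_f`.
#' @param tlc_f Failure criticality `F` in seconds (> 0; vectorised).
#' @param load Cognitive-load indicator, 0 or 1 (vectorised).
#' @return A data frame with columns `mu` (seconds) and `sigma` (seconds).
#' @export
#' @examples
#' eff <- draw_participants(population_params(), 1, seed = 1)
#' eff[, -1] <- as.list(c(population_params()$beta, population_params()$alpha,
#'                        population_params()$gamma))
#' trial_mu_sigma(eff, tlc_f = 2, load = 0) # mu = 0.33 + 0.36*2 = 1.05
trial_mu_sigma <- function(effects, tlc_f, load) {
  if (any(tlc_f <= 0)) stop("`tlc_f` must be > 0 (log link on the spread)")
  if (!all(load %in% c(0, 1))) stop("`load` must be 0 or 1")
  mu <- effects$beta0 + effects$betaF * tlc_f + effects$betaL * load +
    effects$betaFL * tlc_f * load
  sigma <- exp(effects$alpha0 + effects$alphaF * log(tlc_f) +
                 effects$alphaL * load)
  data.frame(mu = mu, sigma = sigma)
}
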