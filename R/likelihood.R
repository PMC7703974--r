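# Model likelihoods, written out explicitly so they can be checked against
# quadrature and used for flat maximum-likelihood cross-checks.

#' Log-likelihood contributions of the takeover-timing model
#'
#' For an observed trial the contribution is the truncated-normal log-density
#' \deqn{\ln \phi((T-\mu)/\sigma) - \ln\sigma - \ln \Phi((F-\mu)/\sigma)}
#' and for a censored trial (no takeover before trial end) the log of the
#' censored probability mass
#' \deqn{\ln \Phi((E-\mu)/\sigma) - \ln \Phi((F-\mu)/\sigma)}
#' where `T` is the observed takeover criticality, `F` the truncation bound
#' (the failure criticality) and `E` the trial-end censoring bound. Both
#' branches are evaluated in log space, so trials with strongly negative `E`
#' simply contribute vanishing censored mass rather than underflowing.
#'
#' @param trials A trial table (columns `tlc_f_s`, `tlc_end_s`, `took_over`,
#'   `tlc_t_s`, `load`, and `participant_id` matching rows of `effects`).
#' @param effects Participant coefficients, one row per participant
#'   (`beta0 ... betaFL`, `alpha0 ... alphaL`), indexed by
#'   `trials$participant_id`; a single row is recycled for all trials.
#' @return A numeric vector of per-trial log-likelihood contributions.
#' @export
loglik_tlc <- function(trials, effects) {
  obs <- trials$took_over
  if (any(obs & trials$tlc_t_s >= trials$tlc_f_s, na.rm = TRUE))
    stop("observed tlc_t_s >= tlc_f_s: violates the truncation bound")
  eff <- if (nrow(effects) == 1L) effects[rep(1L, nrow(trials)), ]
  else effects[match(trials$participant_id, effects$participant_id), ]
  ms <- trial_mu_sigma(eff, trials$tlc_f_s, trials$load)
  if (any(ms$sigma <= 0)) stop("sigma must be > 0")
  ztrunc <- (trials$tlc_f_s - ms$mu) / ms$sigma
  norm <- stats::pnorm(ztrunc, log.p = TRUE)
  ll <- numeric(nrow(trials))
  ll[obs] <- stats::dnorm(trials$tlc_t_s[obs], ms$mu[obs], ms$sigma[obs],
                          log = TRUE) - norm[obs]
  cen <- !obs
  ll[cen] <- stats::pnorm((trials$tlc_end_s[cen] - ms$mu[cen]) / ms$sigma[cen],
                          log.p = TRUE) - norm[cen]
  ll
}

#' Log-likelihood contributions of the steering-correction model
#'
#' Lognormal density of `SWA_Max` on the degree scale (i.e. including the
#' `-ln(swa)` Jacobian of the log transform), with log-mean
#' `gamma0 + gammaT ln(T) + gammaL L + gammaTL ln(T) L`.
#'
#' @param trials Trial table rows with positive `swa_max_deg` and `tlc_t_s`.
#' @param effects Participant coefficients (`gamma0 ... gammaTL`), matched as
#'   in [loglik_tlc()].
#' @param sigma_ln Residual SD on the log scale.
#' @return Per-trial log-density contributions (degree scale).
#' @export
loglik_swa <- function(trials, effects, sigma_ln) {
  if (any(trials$swa_max_deg <= 0, na.rm = TRUE) || anyNA(trials$swa_max_deg))
    stop("`swa_max_deg` must be present and > 0")
  if (any(trials$tlc_t_s <= 0)) stop("`tlc_t_s` must be > 0")
  eff <- if (nrow(effects) == 1L) effects[rep(1L, nrow(trials)), ]
  else effects[match(trials$participant_id, effects$participant_id), ]
  mu_ln <- eff$gamma0 + eff$gammaT * log(trials$tlc_t_s) +
    eff$gammaL * trials$load + eff$gammaTL * log(trials$tlc_t_s) * trials$load
  stats::dnorm(log(trials$swa_max_deg), mu_ln, sigma_ln, log = TRUE) -
    log(trials$swa_max_deg)
}
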