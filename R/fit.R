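# Bayesian fitting of the two hierarchical distributional models via JAGS.

#' Prior specification
#'
#' Weakly informative priors: normal priors on fixed effects, half-normal
#' priors on between-participant SDs and on the steering model's residual SD.
#' Random effects are modelled as independent across coefficients (the
#' between-participant correlations of the generating process default to zero
#' and are not separately identifiable from the published summaries).
#'
#' @param fixed_scale SD of the normal prior on fixed effects (default 2,
#'   on the seconds / log scales the coefficients live on).
#' @param sd_scale Scale of the half-normal prior on random-effect SDs.
#' @param resid_scale Scale of the half-normal prior on the steering model's
#'   log-scale residual SD.
#' @return An object of class `"prior_spec"`.
#' @export
prior_spec <- function(fixed_scale = 2, sd_scale = 1, resid_scale = 1) {
  if (any(c(fixed_scale, sd_scale, resid_scale) <= 0))
    stop("prior scales must be > 0")
  structure(list(fixed_scale = fixed_scale, sd_scale = sd_scale,
                 resid_scale = resid_scale), class = "prior_spec")
}

#' MCMC settings
#'
#' @param chains Number of chains (default 2).
#' @param adapt Adaptation iterations (default 1000).
#' @param warmup Burn-in iterations after adaptation (default 1000).
#' @param draws Retained draws per chain (default 500).
#' @param thin Thinning interval (default 3): `draws * thin` iterations are
#'   run and every `thin`-th is kept, improving mixing per retained draw.
#' @param seed Integer seed; per-chain RNG seeds are derived from it.
#' @return A list of class `"mcmc_control"`.
#' @export
mcmc_control <- function(chains = 2, adapt = 1000, warmup = 1000, draws = 500,
                         thin = 3, seed = 1) {
  stopifnot(chains >= 1, draws >= 1, adapt >= 0, warmup >= 0, thin >= 1)
  structure(list(chains = as.integer(chains), adapt = as.integer(adapt),
                 warmup = as.integer(warmup), draws = as.integer(draws),
                 thin = as.integer(thin), seed = as.integer(seed)),
            class = "mcmc_control")
}

tlc_par_names <- function(load_terms = TRUE, hierarchical = TRUE) {
  fixed <- c("beta0", "betaF", if (load_terms) c("betaL", "betaFL"),
             "alpha0", "alphaF", if (load_terms) "alphaL")
  sds <- if (hierarchical) paste0("sd_", fixed) else character()
  list(fixed = fixed, sds = sds)
}

swa_par_names <- function(load_terms = TRUE, hierarchical = TRUE) {
  fixed <- c("gamma0", "gammaT", if (load_terms) c("gammaL", "gammaTL"))
  sds <- if (hierarchical) paste0("sd_", fixed) else character()
  list(fixed = fixed, sds = sds)
}

# Build the JAGS model string for the truncated/censored TLC_T model.
# Loops over zero-length data blocks are omitted (JAGS rejects 1:0 loops).
jags_tlc_model <- function(n_obs, n_cen, nb, na, hierarchical, priors) {
  tf <- 1 / priors$fixed_scale^2
  ts <- 1 / priors$sd_scale^2
  lin <- function(suffix) {
    bt <- if (hierarchical) "bj[pid%s[i], %d]" else "b[%d]"
    at <- if (hierarchical) "aj[pid%s[i], %d]" else "a[%d]"
    term <- function(tmpl, k) if (hierarchical) sprintf(tmpl, suffix, k)
      else sprintf(tmpl, k)
    mu <- paste0(term(bt, 1), " + ", term(bt, 2), sprintf(" * F%s[i]", suffix))
    if (nb == 4L)
      mu <- paste0(mu, " + ", term(bt, 3), sprintf(" * L%s[i]", suffix),
                   " + ", term(bt, 4), sprintf(" * F%s[i] * L%s[i]", suffix, suffix))
    ls <- paste0(term(at, 1), " + ", term(at, 2), sprintf(" * lF%s[i]", suffix))
    if (na == 3L) ls <- paste0(ls, " + ", term(at, 3), sprintf(" * L%s[i]", suffix))
    list(mu = mu, ls = ls)
  }
  obs_block <- if (n_obs > 0) {
    l <- lin("o")
    sprintf("
  for (i in 1:No) {
    muo[i] <- %s
    tauo[i] <- exp(-2 * (%s))
    yo[i] ~ dnorm(muo[i], tauo[i]) T(, Fo[i])
  }", l$mu, l$ls)
  } else ""
  cen_block <- if (n_cen > 0) {
    l <- lin("c")
    sprintf("
  for (i in 1:Nc) {
    muc[i] <- %s
    tauc[i] <- exp(-2 * (%s))
    censind[i] ~ dinterval(yc[i], Ec[i])
    yc[i] ~ dnorm(muc[i], tauc[i]) T(, Fc[i])
  }", l$mu, l$ls)
  } else ""
  re_block <- if (hierarchical) sprintf("
  for (p in 1:P) {
    for (k in 1:%d) { bj[p, k] ~ dnorm(b[k], pow(sdb[k], -2)) }
    for (k in 1:%d) { aj[p, k] ~ dnorm(a[k], pow(sda[k], -2)) }
  }
  for (k in 1:%d) { sdb[k] ~ dnorm(0, %g) T(0,) }
  for (k in 1:%d) { sda[k] ~ dnorm(0, %g) T(0,) }",
    nb, na, nb, ts, na, ts) else ""
  sprintf("model {%s%s%s
  for (k in 1:%d) { b[k] ~ dnorm(0, %g) }
  for (k in 1:%d) { a[k] ~ dnorm(0, %g) }
}", obs_block, cen_block, re_block, nb, tf, na, tf)
}

jags_swa_model <- function(n_obs, ng, hierarchical, priors) {
  tf <- 1 / priors$fixed_scale^2
  ts <- 1 / priors$sd_scale^2
  tr <- 1 / priors$resid_scale^2
  gt <- if (hierarchical) "gj[pid[i], %d]" else "g[%d]"
  term <- function(k) sprintf(gt, k)
  mu <- paste0(term(1), " + ", term(2), " * lT[i]")
  if (ng == 4L)
    mu <- paste0(mu, " + ", term(3), " * L[i] + ", term(4), " * lT[i] * L[i]")
  obs_block <- if (n_obs > 0) sprintf("
  for (i in 1:N) {
    mu[i] <- %s
    ly[i] ~ dnorm(mu[i], tauy)
  }", mu) else ""
  re_block <- if (hierarchical) sprintf("
  for (p in 1:P) {
    for (k in 1:%d) { gj[p, k] ~ dnorm(g[k], pow(sdg[k], -2)) }
  }
  for (k in 1:%d) { sdg[k] ~ dnorm(0, %g) T(0,) }", ng, ng, ts) else ""
  sprintf("model {%s%s
  for (k in 1:%d) { g[k] ~ dnorm(0, %g) }
  tauy <- pow(sigma, -2)
  sigma ~ dnorm(0, %g) T(0,)
}", obs_block, re_block, ng, tf, tr)
}

run_jags <- function(model_string, data, inits_extra, monitor, control,
                     quiet = TRUE) {
  inits <- lapply(seq_len(control$chains), function(ch) {
    c(inits_extra,
      list(.RNG.name = "base::Mersenne-Twister",
           .RNG.seed = control$seed * 1000L + ch))
  })
  maybe_muffle <- function(expr) {
    if (!quiet) return(expr)
    withCallingHandlers(expr, warning = function(w) {
      if (grepl("[Aa]daptation", conditionMessage(w)))
        invokeRestart("muffleWarning")
    })
  }
  m <- maybe_muffle(
    rjags::jags.model(textConnection(model_string), data = data,
                      inits = inits, n.chains = control$chains,
                      n.adapt = control$adapt, quiet = quiet))
  if (control$warmup > 0) stats::update(m, control$warmup,
                                        progress.bar = "none")
  thin <- if (is.null(control$thin)) 1L else control$thin
  rjags::coda.samples(m, monitor, n.iter = control$draws * thin, thin = thin,
                      progress.bar = "none")
}

rename_draws <- function(samples, map) {
  for (i in seq_along(samples)) {
    cn <- colnames(samples[[i]])
    hit <- match(cn, names(map))
    cn[!is.na(hit)] <- map[hit[!is.na(hit)]]
    colnames(samples[[i]]) <- cn
  }
  samples
}

fit_diagnostics <- function(samples, params) {
  sub <- samples[, params, drop = FALSE]
  ess <- coda::effectiveSize(sub)
  rhat <- if (coda::nchain(samples) > 1)
    coda::gelman.diag(sub, multivariate = FALSE, autoburnin = FALSE)$psrf[, 1]
  else rep(NA_real_, length(params))
  names(rhat) <- params
  list(rhat = rhat, ess = ess,
       max_rhat = if (all(is.na(rhat))) NA_real_ else max(rhat, na.rm = TRUE),
       min_ess = min(ess))
}

new_takeover_fit <- function(model, samples, pars, diag, data_info, priors,
                             control, call) {
  conv <- is.na(diag$max_rhat) || diag$max_rhat <= 1.05
  if (!conv)
    warning(sprintf("convergence gate: max split-Rhat %.3f exceeds 1.05; %s",
                    diag$max_rhat, "increase warmup/draws"), call. = FALSE)
  structure(list(model = model, samples = samples, pars = pars,
                 diagnostics = diag, converged = conv, data_info = data_info,
                 priors = priors, control = control, call = call),
            class = "takeover_fit")
}

#' Fit the hierarchical takeover-timing model
#'
#' Fits the truncated/censored heteroscedastic model of takeover criticality:
#' observed `TLC_T` follows a normal distribution with a linear mean submodel
#' in `TLC_F` and load, and a log-linear spread submodel in `ln(TLC_F)` and
#' load; the distribution is truncated above at each trial's own `TLC_F` and
#' censored below at its `TLC_End`. Participant-level coefficients are given
#' independent normal random effects around the population values (centred
#' parameterisation). Sampling is by Gibbs/slice MCMC in JAGS; censored trials
#' carry latent responses constrained below their censoring bound.
#'
#' @param trials Trial table (see [generate_study()] / [read_trials()]);
#'   pre-onset takeovers must already have been removed (see
#'   [apply_exclusions()]).
#' @param priors A [prior_spec()].
#' @param control An [mcmc_control()].
#' @param load_terms If `FALSE`, drop the load terms (`betaL`, `betaFL`,
#'   `alphaL`) and fit the no-load submodel.
#' @param hierarchical If `FALSE`, drop the participant random effects and
#'   fit a flat (complete-pooling) model.
#' @param quiet Suppress JAGS progress output.
#' @return An object of class `"takeover_fit"`. Use [summary()] for the
#'   posterior-mean/HDI table, [coef()] for posterior means of fixed effects,
#'   [predict()] and [p_exit()] for posterior predictions.
#' @export
fit_tlc <- function(trials, priors = prior_spec(), control = mcmc_control(),
                    load_terms = TRUE, hierarchical = TRUE, quiet = TRUE) {
  if (any(!is.na(trials$rt_s) & trials$rt_s < 0))
    stop("trials contain pre-onset takeovers; run apply_exclusions() first")
  obs <- trials$took_over
  if (any(obs & trials$tlc_t_s >= trials$tlc_f_s))
    stop("observed tlc_t_s >= tlc_f_s: violates the truncation bound")
  pid_levels <- sort(unique(trials$participant_id))
  if (hierarchical && length(pid_levels) < 2 && nrow(trials) > 0)
    stop("hierarchical fit needs at least 2 participants")
  pid <- match(trials$participant_id, pid_levels)
  nb <- if (load_terms) 4L else 2L
  na <- if (load_terms) 3L else 2L

  o <- which(obs); cn <- which(!obs)
  dat <- list(P = length(pid_levels))
  if (length(o)) dat <- c(dat, list(
    No = length(o), pido = pid[o], Fo = trials$tlc_f_s[o],
    lFo = log(trials$tlc_f_s[o]), yo = trials$tlc_t_s[o]))
  if (length(o) && load_terms) dat$Lo <- trials$load[o]
  if (length(cn)) dat <- c(dat, list(
    Nc = length(cn), pidc = pid[cn], Fc = trials$tlc_f_s[cn],
    lFc = log(trials$tlc_f_s[cn]), Ec = trials$tlc_end_s[cn],
    censind = rep(0L, length(cn))))
  if (length(cn) && load_terms) dat$Lc <- trials$load[cn]
  if (!hierarchical) dat$P <- NULL
  if (!load_terms) { dat$Lo <- NULL; dat$Lc <- NULL }

  inits_extra <- if (length(cn))
    list(yc = pmin(trials$tlc_end_s[cn], trials$tlc_f_s[cn]) - 0.5)
  else list()

  mstr <- jags_tlc_model(length(o), length(cn), nb, na, hierarchical, priors)
  monitor <- c("b", "a", if (hierarchical) c("sdb", "sda", "bj", "aj"))
  samples <- run_jags(mstr, dat, inits_extra, monitor, control, quiet)

  nm <- tlc_par_names(load_terms, hierarchical)
  map <- c(stats::setNames(nm$fixed,
                           c(paste0("b[", 1:nb, "]"), paste0("a[", 1:na, "]"))),
           if (hierarchical)
             stats::setNames(nm$sds, c(paste0("sdb[", 1:nb, "]"),
                                       paste0("sda[", 1:na, "]"))))
  samples <- rename_draws(samples, map)
  diag <- fit_diagnostics(samples, c(nm$fixed, nm$sds))
  info <- list(n_obs = length(o), n_censored = length(cn),
               n_participants = length(pid_levels), pid_levels = pid_levels,
               load_terms = load_terms, hierarchical = hierarchical,
               tlc_f_range = range(trials$tlc_f_s))
  new_takeover_fit("tlc", samples, nm, diag, info, priors, control,
                   match.call())
}

#' Fit the hierarchical steering-correction model
#'
#' Fits the lognormal power-law model of the maximum steering correction:
#' `ln(SWA_Max)` is normal with mean linear in `ln(TLC_T)`, load, and their
#' interaction, and a common residual SD. Participant coefficients get
#' independent normal random effects. Trials without an observed takeover,
#' with an invalidated steering correction, or with non-positive `TLC_T` are
#' dropped (with a message).
#'
#' @inheritParams fit_tlc
#' @return An object of class `"takeover_fit"` (model `"swa"`).
#' @export
fit_swa <- function(trials, priors = prior_spec(), control = mcmc_control(),
                    load_terms = TRUE, hierarchical = TRUE, quiet = TRUE) {
  use <- trials$took_over & !is.na(trials$swa_max_deg) &
    !trials$swa_invalid & !is.na(trials$tlc_t_s) & trials$tlc_t_s > 0
  dropped <- nrow(trials) - sum(use)
  if (dropped > 0 && !quiet)
    message(sprintf("dropping %d trials without a valid steering correction",
                    dropped))
  tr <- trials[use, , drop = FALSE]
  pid_levels <- sort(unique(tr$participant_id))
  if (hierarchical && length(pid_levels) < 2 && nrow(tr) > 0)
    stop("hierarchical fit needs at least 2 participants")
  ng <- if (load_terms) 4L else 2L

  dat <- list(P = length(pid_levels))
  if (nrow(tr)) dat <- c(dat, list(
    N = nrow(tr), pid = match(tr$participant_id, pid_levels),
    lT = log(tr$tlc_t_s), ly = log(tr$swa_max_deg)))
  if (nrow(tr) && load_terms) dat$L <- tr$load
  if (!hierarchical) { dat$P <- NULL; dat$pid <- NULL }

  mstr <- jags_swa_model(nrow(tr), ng, hierarchical, priors)
  monitor <- c("g", "sigma", if (hierarchical) c("sdg", "gj"))
  samples <- run_jags(mstr, dat, list(), monitor, control, quiet)

  nm <- swa_par_names(load_terms, hierarchical)
  map <- stats::setNames(nm$fixed, paste0("g[", 1:ng, "]"))
  if (hierarchical)
    map <- c(map, stats::setNames(nm$sds, paste0("sdg[", 1:ng, "]")))
  samples <- rename_draws(samples, map)
  diag <- fit_diagnostics(samples, c(nm$fixed, nm$sds, "sigma"))
  info <- list(n_obs = nrow(tr), n_censored = 0L, n_dropped = dropped,
               n_participants = length(pid_levels), pid_levels = pid_levels,
               load_terms = load_terms, hierarchical = hierarchical,
               tlc_t_range = if (nrow(tr)) range(tr$tlc_t_s) else c(NA, NA))
  new_takeover_fit("swa", samples, nm, diag, info, priors, control,
                   match.call())
}

#' Highest density interval
#'
#' Narrowest contiguous interval containing the requested posterior mass,
#' computed from samples by the shortest sorted window.
#'
#' @param x Numeric vector of samples (>= 100 recommended).
#' @param mass Probability mass (default 0.95).
#' @return Named numeric vector `c(lower, upper)`.
#' @export
#' @examples
#' hdi(rnorm(1e5)) # about (-1.96, 1.96)
hdi <- function(x, mass = 0.95) {
  if (mass <= 0 || mass > 1) stop("`mass` must be in (0, 1]")
  x <- sort(x[is.finite(x)])
  n <- length(x)
  if (n == 0) stop("no finite samples")
  k <- max(1L, ceiling(mass * n))
  if (k >= n) return(c(lower = x[1], upper = x[n]))
  width <- x[(k + 1):n] - x[1:(n - k)]
  i <- which.min(width)
  c(lower = x[i], upper = x[i + k])
}

#' Posterior draws as a matrix
#'
#' @param x A `"takeover_fit"`.
#' @param ... Unused.
#' @return Matrix with one column per monitored parameter, chains stacked.
#' @export
as.matrix.takeover_fit <- function(x, ...) as.matrix(x$samples)

#' Posterior means of the fixed effects
#'
#' @param object A `"takeover_fit"`.
#' @param ... Unused.
#' @return Named numeric vector of posterior means.
#' @export
coef.takeover_fit <- function(object, ...) {
  colMeans(as.matrix(object)[, object$pars$fixed, drop = FALSE])
}

#' @export
print.takeover_fit <- function(x, ...) {
  kind <- if (x$model == "tlc") "takeover timing (truncated/censored normal)"
  else "maximum steering correction (lognormal power law)"
  cat(sprintf("Hierarchical Bayesian model of %s\n", kind))
  cat(sprintf("  %d observed trials%s, %d participants\n", x$data_info$n_obs,
              if (x$model == "tlc")
                sprintf(" + %d censored", x$data_info$n_censored) else "",
              x$data_info$n_participants))
  cat(sprintf("  %d chains x %d draws; max split-Rhat %.3f, min ESS %.0f%s\n",
              x$control$chains, x$control$draws,
              x$diagnostics$max_rhat, x$diagnostics$min_ess,
              if (!x$converged) "  [convergence warning]" else ""))
  cat("\nPosterior means of fixed effects:\n")
  print(round(coef(x), 3))
  invisible(x)
}

# Parameters whose exponentiated twin is reported (multiplicative scale).
exp_twins <- c("alpha0", "alphaL", "gamma0", "gammaT", "gammaL", "gammaTL")

#' Posterior summary table
#'
#' Posterior means and 95% highest density intervals for the fixed effects
#' and random-effect SDs, with exponentiated twins (computed draw-wise, then
#' summarised) for coefficients that act multiplicatively.
#'
#' @param object A `"takeover_fit"`.
#' @param mass HDI mass (default 0.95).
#' @param ... Unused.
#' @return A data frame of class `"summary.takeover_fit"` with columns
#'   `parameter`, `mean`, `lower`, `upper`, `exp_mean`, `exp_lower`,
#'   `exp_upper` (NA where no twin is reported).
#' @export
summary.takeover_fit <- function(object, mass = 0.95, ...) {
  dr <- as.matrix(object)
  pars <- c(object$pars$fixed, object$pars$sds,
            if (object$model == "swa") "sigma")
  rows <- lapply(pars, function(p) {
    v <- dr[, p]
    h <- hdi(v, mass)
    ex <- if (p %in% exp_twins) {
      eh <- hdi(exp(v), mass)
      c(mean(exp(v)), eh[1], eh[2])
    } else c(NA_real_, NA_real_, NA_real_)
    data.frame(parameter = p, mean = mean(v), lower = h[1], upper = h[2],
               exp_mean = ex[1], exp_lower = ex[2], exp_upper = ex[3])
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "model") <- object$model
  attr(out, "mass") <- mass
  class(out) <- c("summary.takeover_fit", "data.frame")
  out
}

#' @export
print.summary.takeover_fit <- function(x, digits = 3, ...) {
  cat(sprintf("Posterior means and %.1f%% HDIs (%s model)\n",
              100 * attr(x, "mass"),
              if (attr(x, "model") == "tlc") "takeover timing" else "steering"))
  df <- as.data.frame(x)
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], round, digits)
  print(df, row.names = FALSE)
  invisible(x)
}

#' Randomised quantile residuals
#'
#' Probability-integral-transform residuals evaluated at the posterior means
#' of the participant-level coefficients: for the timing model, the truncated
#' normal CDF of each observed `TLC_T` mapped through the standard normal
#' quantile function (censored trials return `NA`); for the steering model,
#' standardised log-scale residuals. Under a well-specified model these are
#' approximately standard normal.
#'
#' @param object A `"takeover_fit"`.
#' @param trials The trial table the model was fitted to.
#' @param ... Unused.
#' @return Numeric vector, one element per row of `trials`.
#' @export
residuals.takeover_fit <- function(object, trials, ...) {
  eff <- participant_means(object)
  if (object$model == "tlc") {
    idx <- match(trials$participant_id, object$data_info$pid_levels)
    e <- eff[idx, , drop = FALSE]
    ms <- trial_mu_sigma(e, trials$tlc_f_s, trials$load)
    z <- (trials$tlc_t_s - ms$mu) / ms$sigma
    cap <- stats::pnorm((trials$tlc_f_s - ms$mu) / ms$sigma)
    out <- stats::qnorm(stats::pnorm(z) / cap)
    out[!trials$took_over] <- NA_real_
    out
  } else {
    use <- trials$took_over & !is.na(trials$swa_max_deg) &
      !is.na(trials$tlc_t_s) & trials$tlc_t_s > 0
    use[is.na(use)] <- FALSE
    idx <- match(trials$participant_id, object$data_info$pid_levels)
    e <- eff[idx, , drop = FALSE]
    mu_ln <- e$gamma0 + e$gammaT * log(trials$tlc_t_s) +
      e$gammaL * trials$load + e$gammaTL * log(trials$tlc_t_s) * trials$load
    sig <- mean(as.matrix(object)[, "sigma"])
    out <- (log(trials$swa_max_deg) - mu_ln) / sig
    out[!use] <- NA_real_
    out
  }
}

# Posterior means of participant-level coefficients, one row per participant.
participant_means <- function(object) {
  dr <- as.matrix(object)
  P <- object$data_info$n_participants
  nm <- object$pars$fixed
  if (!object$data_info$hierarchical) {
    out <- as.data.frame(as.list(colMeans(dr[, nm, drop = FALSE])))
    return(out[rep(1L, max(P, 1L)), , drop = FALSE])
  }
  if (object$model == "tlc") {
    nb <- sum(grepl("^beta", nm)); na <- sum(grepl("^alpha", nm))
    cols <- c(outer(seq_len(P), seq_len(nb),
                    function(p, k) sprintf("bj[%d,%d]", p, k)),
              outer(seq_len(P), seq_len(na),
                    function(p, k) sprintf("aj[%d,%d]", p, k)))
    m <- matrix(colMeans(dr[, cols, drop = FALSE]), nrow = P)
  } else {
    ng <- length(nm)
    cols <- outer(seq_len(P), seq_len(ng),
                  function(p, k) sprintf("gj[%d,%d]", p, k))
    m <- matrix(colMeans(dr[, cols, drop = FALSE]), nrow = P)
  }
  out <- as.data.frame(m)
  names(out) <- nm
  out
}
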