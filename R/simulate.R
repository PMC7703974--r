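# Synthetic takeover-study generation: the stand-in for raw simulator data.

# Inverse-CDF quantile of a standard normal truncated above at `b`, evaluated
# in log space so that deep truncation (b far below 0) stays finite.
qtrunc_upper <- function(u, b) {
  stats::qnorm(log(u) + stats::pnorm(b, log.p = TRUE), log.p = TRUE)
}

#' Takeover study design
#'
#' The mixed design combines a small set of Repeated failure conditions
#' (several repetitions each, to pin down central tendency and variability)
#' with a Sobol-generated pool of Non-Repeated conditions spanning a wider
#' criticality range (to keep failures unpredictable). Each participant
#' completes every condition under both load conditions and both bend
#' directions. With the defaults this yields
#' 2 loads x 2 directions x (6 x 4 Repeated + 24 Non-Repeated) = 192 trials
#' per participant across 28 distinct failure conditions.
#'
#' @param n_participants Number of participants (default 20).
#' @param repeated_reps Repetitions of each Repeated condition per load and
#'   bend direction (default 6).
#' @param n_nonrepeated Number of Non-Repeated conditions (default 24).
#' @param trial_length Trial length in seconds (default 15).
#' @param dropout Number of participants flagged as excluded wholesale
#'   (default 0). Flagged participants are generated and marked, mirroring
#'   study-level exclusions, but carry `participant_excluded = TRUE`.
#' @param ... Passed to [failure_conditions()] (criticality and onset ranges,
#'   understeer fraction, Sobol skip, ...).
#' @return An object of class `"study_design"`: a list with the condition
#'   table (`conditions`), counts, and `trial_length`.
#' @export
study_design <- function(n_participants = 20, repeated_reps = 6,
                         n_nonrepeated = 24, trial_length = 15, dropout = 0,
                         ...) {
  if (n_participants <= 0) stop("`n_participants` must be > 0")
  conds <- failure_conditions(n_nonrepeated = n_nonrepeated,
                              solve_offsets = FALSE, ...)
  n_rep <- sum(conds$repeated_flag)
  trials_pp <- 2 * 2 * (repeated_reps * n_rep + n_nonrepeated)
  structure(list(conditions = conds, n_participants = n_participants,
                 repeated_reps = repeated_reps, trials_per_participant = trials_pp,
                 trial_length = trial_length, dropout = dropout),
            class = "study_design")
}

#' @export
print.study_design <- function(x, ...) {
  cat(sprintf(paste0("Takeover study design: %d participants, %d failure ",
                     "conditions (%d Repeated x %d reps + %d Non-Repeated), ",
                     "%d trials/participant, %g s trials\n"),
              x$n_participants, nrow(x$conditions), sum(x$conditions$repeated_flag),
              x$repeated_reps, sum(!x$conditions$repeated_flag),
              x$trials_per_participant, x$trial_length))
  invisible(x)
}

#' Sample takeover criticality for one or more trials
#'
#' Draws from a normal distribution truncated above at the failure
#' criticality `tlc_f` (a response cannot adopt more margin than the failure
#' allows), then applies trial-end censoring on the latent scale: draws below
#' `tlc_end` mean the driver would have taken over after the trial ended, so
#' no takeover is observed. Sampling uses the inverse-CDF transform, so the
#' generator and the model likelihood agree exactly.
#'
#' With `sigma = 0` the draw is degenerate at `mu` (clamped to `tlc_f`).
#'
#' @param mu,sigma Trial-level mean and SD in seconds (vectorised).
#' @param tlc_f Truncation bound (failure criticality) in seconds.
#' @param tlc_end Censoring bound in seconds (may be negative, in which case
#'   censoring never binds).
#' @param seed Optional integer seed.
#' @return A data frame with columns `tlc_t` (seconds; `NA` when censored)
#'   and `took_over` (logical).
#' @export
sample_tlc_t <- function(mu, sigma, tlc_f, tlc_end, seed = NULL) {
  if (any(sigma < 0)) stop("`sigma` must be >= 0")
  if (!is.null(seed)) set.seed(seed)
  n <- max(length(mu), length(sigma), length(tlc_f), length(tlc_end))
  mu <- rep_len(mu, n); sigma <- rep_len(sigma, n)
  tlc_f <- rep_len(tlc_f, n); tlc_end <- rep_len(tlc_end, n)
  draw <- numeric(n)
  deg <- sigma == 0
  draw[deg] <- pmin(mu[deg], tlc_f[deg])
  if (any(!deg)) {
    u <- stats::runif(sum(!deg))
    draw[!deg] <- mu[!deg] + sigma[!deg] *
      qtrunc_upper(u, (tlc_f[!deg] - mu[!deg]) / sigma[!deg])
  }
  censored <- draw < tlc_end
  data.frame(tlc_t = ifelse(censored, NA_real_, draw), took_over = !censored)
}

#' Sample maximum steering correction
#'
#' Draws `SWA_Max` (degrees) from the lognormal power-law model: the log-mean
#' is `gamma0 + gammaT*ln(T) + gammaL*L + gammaTL*ln(T)*L`, so the geometric
#' mean at `T = 1` s without load is `exp(gamma0)`.
#'
#' @param effects Participant coefficient rows (recycled against `tlc_t`).
#' @param tlc_t Criticality at takeover in seconds (> 0).
#' @param load Load indicator, 0 or 1.
#' @param sigma_ln Residual SD on the log scale.
#' @param seed Optional integer seed.
#' @return Steering corrections in degrees (> 0).
#' @export
sample_swa_max <- function(effects, tlc_t, load, sigma_ln = 0.35, seed = NULL) {
  if (any(tlc_t <= 0)) stop("`tlc_t` must be > 0 (log-log model)")
  if (!is.null(seed)) set.seed(seed)
  mu_ln <- effects$gamma0 + effects$gammaT * log(tlc_t) +
    effects$gammaL * load + effects$gammaTL * log(tlc_t) * load
  exp(stats::rnorm(length(mu_ln), mu_ln, sigma_ln))
}

#' Generate a synthetic takeover study
#'
#' Builds the full trial table for a synthetic study: draws participant
#' coefficients from the population, evaluates the trial-level location and
#' scale for every condition x load x direction (x repetition) cell, samples
#' truncated/censored takeover criticalities and lognormal steering
#' corrections, and computes each trial's censoring threshold from the
#' trial-length bookkeeping (`tlc_end = tlc_f - (trial_length - onset)`).
#' Deterministic for a fixed seed.
#'
#' @param pop A [population_params()] object (defaults to the published
#'   posterior means).
#' @param design A [study_design()] object.
#' @param seed Integer seed (required; no silent time-based seeding).
#' @param noise_free If `TRUE`, zero all random-effect SDs and the trial
#'   noise, so every response equals its population mean (used for structural
#'   identities such as the reaction-time slope `1 - betaF`).
#' @return A data frame with one row per trial: `participant_id`, `load`,
#'   `condition_id`, `repeated`, `direction`, `tlc_f_s`, `onset_s`,
#'   `tlc_end_s`, `took_over`, `tlc_t_s`, `rt_s`, `swa_max_deg`,
#'   `excluded_pre_onset`, `swa_invalid`, `participant_excluded`.
#' @export
#' @examples
#' trials <- generate_study(design = study_design(n_participants = 2), seed = 1)
#' nrow(trials) # 2 x 192
generate_study <- function(pop = population_params(), design = study_design(),
                           seed, noise_free = FALSE) {
  stopifnot(inherits(pop, "population_params"), inherits(design, "study_design"))
  if (missing(seed)) stop("`seed` is required for reproducibility")
  set.seed(seed)

  if (noise_free) {
    pop$sd_beta[] <- 0; pop$sd_alpha[] <- 0; pop$sd_gamma[] <- 0
    pop$sigma_swa <- 0
  }
  eff <- draw_participants(pop, design$n_participants)

  conds <- design$conditions
  reps <- ifelse(conds$repeated_flag, design$repeated_reps, 1L)
  cell <- conds[rep(seq_len(nrow(conds)), reps), ]
  grid <- expand.grid(cell_row = seq_len(nrow(cell)), load = c(0L, 1L),
                      bend = c("left", "right"), KEEP.OUT.ATTRS = FALSE,
                      stringsAsFactors = FALSE)

  out <- vector("list", design$n_participants)
  for (p in seq_len(design$n_participants)) {
    tf <- cell$tlc_f_s[grid$cell_row]
    on <- cell$onset_s[grid$cell_row]
    ms <- trial_mu_sigma(eff[p, ], tf, grid$load)
    if (noise_free) ms$sigma[] <- 0
    te <- tlc_end(tf, on, design$trial_length)
    resp <- sample_tlc_t(ms$mu, ms$sigma, tf, te)
    swa <- rep(NA_real_, nrow(grid))
    ok <- resp$took_over & !is.na(resp$tlc_t) & resp$tlc_t > 0
    if (any(ok))
      swa[ok] <- sample_swa_max(eff[p, ], resp$tlc_t[ok], grid$load[ok],
                                sigma_ln = pop$sigma_swa)
    rt <- tf - resp$tlc_t
    out[[p]] <- data.frame(
      participant_id = p, load = grid$load,
      condition_id = cell$condition_id[grid$cell_row],
      repeated = cell$repeated_flag[grid$cell_row],
      direction = grid$bend,
      tlc_f_s = tf, onset_s = on, tlc_end_s = te,
      took_over = resp$took_over, tlc_t_s = resp$tlc_t, rt_s = rt,
      swa_max_deg = swa,
      excluded_pre_onset = FALSE, swa_invalid = FALSE,
      participant_excluded = p > design$n_participants - design$dropout)
  }
  trials <- do.call(rbind, out)
  rownames(trials) <- NULL
  attr(trials, "seed") <- seed
  trials
}

#' Apply the study's trial-exclusion rules
#'
#' Two rules are applied. (1) Trials where the driver took over before the
#' failure onset (negative reaction time) are removed from all analyses.
#' (2) Trials where the driver took over with less than `min_remaining_for_swa`
#' seconds of the trial remaining are kept for the timing analysis but their
#' steering correction is invalidated (`swa_max_deg` set to `NA`,
#' `swa_invalid` flagged): the initial steering correction cannot complete in
#' such a short window.
#'
#' @param trials A trial table as produced by [generate_study()] or
#'   [read_trials()].
#' @param min_remaining_for_swa Minimum trial time remaining after takeover
#'   for a valid steering correction, in seconds (default 0.25).
#' @param trial_length Trial length in seconds (default 15).
#' @return A list of class `"exclusion_result"` with elements `trials` (the
#'   filtered table) and `report` (counts per rule).
#' @export
apply_exclusions <- function(trials, min_remaining_for_swa = 0.25,
                             trial_length = 15) {
  n0 <- nrow(trials)
  pre <- !is.na(trials$rt_s) & trials$rt_s < 0
  trials$excluded_pre_onset <- pre
  kept <- trials[!pre, , drop = FALSE]

  remaining <- trial_length - kept$onset_s - kept$rt_s
  late <- kept$took_over & !is.na(remaining) & remaining < min_remaining_for_swa
  n_swa_invalid <- sum(late & !is.na(kept$swa_max_deg))
  kept$swa_invalid <- kept$swa_invalid | late
  kept$swa_max_deg[late] <- NA_real_

  report <- list(n_trials = n0, n_pre_onset = sum(pre),
                 pct_pre_onset = 100 * sum(pre) / n0,
                 n_swa_invalid = sum(late), n_swa_removed = n_swa_invalid,
                 n_censored = sum(!kept$took_over),
                 pct_observed = 100 * mean(kept$took_over))
  structure(list(trials = kept, report = report), class = "exclusion_result")
}

#' @export
print.exclusion_result <- function(x, ...) {
  r <- x$report
  cat(sprintf("Exclusions: %d/%d trials pre-onset (%.1f%%) removed;\n",
              r$n_pre_onset, r$n_trials, r$pct_pre_onset))
  cat(sprintf("  %d takeovers within the final window (SWA_Max invalidated);\n",
              r$n_swa_invalid))
  cat(sprintf("  %d censored trials (takeover observed in %.1f%% of trials)\n",
              r$n_censored, r$pct_observed))
  invisible(x)
}
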