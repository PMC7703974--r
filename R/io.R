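# Trial-table CSV round trips, steering-trace feature extraction, and run
# configuration.

trial_columns <- c("participant_id", "load", "tlc_f_s", "onset_s", "tlc_end_s",
                   "took_over", "tlc_t_s", "rt_s", "swa_max_deg",
                   "excluded_pre_onset", "swa_invalid")

#' Write a trial table to CSV
#'
#' @param trials A trial table (see [generate_study()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_trials <- function(trials, path) {
  miss <- setdiff(trial_columns, names(trials))
  if (length(miss))
    stop("missing required columns: ", paste(miss, collapse = ", "))
  utils::write.csv(trials, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Read and validate a trial table from CSV
#'
#' Validates the schema (required columns, numeric fields, logical flags) and
#' the structural invariants of a takeover trial: an observed takeover must
#' satisfy `tlc_t_s < tlc_f_s` (the truncation bound) and censored trials
#' must not carry a `tlc_t_s`. Validation failures name the offending row.
#'
#' @param path CSV path.
#' @return A trial table data frame. A header-only file yields an empty
#'   table, not an error.
#' @export
read_trials <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  miss <- setdiff(trial_columns, names(df))
  if (length(miss))
    stop("missing required columns: ", paste(miss, collapse = ", "))
  if (nrow(df) == 0) return(df)
  num_cols <- c("tlc_f_s", "onset_s", "tlc_end_s", "tlc_t_s", "rt_s",
                "swa_max_deg", "load")
  for (cc in num_cols) {
    v <- df[[cc]]
    if (is.character(v)) v[v == ""] <- NA
    suppressWarnings(vn <- as.numeric(v))
    bad <- which(!is.na(v) & is.na(vn))
    if (length(bad))
      stop(sprintf("non-numeric value in column `%s` at row %d", cc, bad[1]))
    df[[cc]] <- vn
  }
  for (cc in c("took_over", "excluded_pre_onset", "swa_invalid"))
    df[[cc]] <- as.logical(df[[cc]])
  bad <- which(df$took_over & !is.na(df$tlc_t_s) & df$tlc_t_s >= df$tlc_f_s)
  if (length(bad))
    stop(sprintf("tlc_t_s >= tlc_f_s at row %d: violates the truncation bound",
                 bad[1]))
  bad <- which(df$took_over & is.na(df$tlc_t_s))
  if (length(bad))
    stop(sprintf("took_over without tlc_t_s at row %d", bad[1]))
  df
}

#' Extract the maximum steering correction from a steering trace
#'
#' The magnitude of the initial corrective steering manoeuvre: the largest
#' unsigned deviation of the steering-wheel angle from its value at takeover,
#' within a fixed window after the takeover. Samples beyond the window are
#' ignored (late peaks do not count).
#'
#' @param time Sample times in seconds (uniform sampling assumed).
#' @param swa Steering-wheel angle in degrees (signed), same length.
#' @param takeover_time Takeover instant in seconds, within the trace span.
#' @param window Window length in seconds after takeover (default 2).
#' @return Correction magnitude in degrees, or `NA` if no samples fall in
#'   the window.
#' @export
#' @examples
#' t <- seq(0, 4, by = 1/60)
#' swa_max_from_trace(t, 10 * pmax(t - 1, 0), takeover_time = 1) # 20
swa_max_from_trace <- function(time, swa, takeover_time, window = 2) {
  if (window <= 0) stop("`window` must be > 0")
  if (length(time) != length(swa)) stop("`time` and `swa` lengths differ")
  at <- which(time >= takeover_time)
  if (!length(at)) return(NA_real_)
  swa0 <- swa[at[1]]
  inwin <- time >= takeover_time & time <= takeover_time + window
  if (!any(inwin)) return(NA_real_)
  max(abs(swa[inwin] - swa0))
}

#' Read a run configuration
#'
#' YAML configuration with blocks `geometry`, `population`, `design`,
#' `priors`, `mcmc`, `prediction` and a top-level `seed`. Unknown top-level
#' keys are rejected. Blocks map onto the corresponding constructors
#' ([road_geometry()], [population_params()], [study_design()],
#' [prior_spec()], [mcmc_control()]).
#'
#' @param path Path to a YAML file.
#' @return A named list with constructed objects (absent blocks yield
#'   defaults) and the `seed`.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  known <- c("geometry", "population", "design", "priors", "mcmc",
             "prediction", "seed")
  unknown <- setdiff(names(cfg), known)
  if (length(unknown))
    stop("unknown configuration keys: ", paste(unknown, collapse = ", "))
  build <- function(block, fun) do.call(fun, if (is.null(cfg[[block]]))
    list() else cfg[[block]])
  list(geometry = build("geometry", road_geometry),
       population = build("population", population_params),
       design = build("design", study_design),
       priors = build("priors", prior_spec),
       mcmc = build("mcmc", mcmc_control),
       prediction = if (is.null(cfg$prediction)) list() else cfg$prediction,
       seed = cfg$seed)
}

#' Write posterior draws to CSV
#'
#' One row per draw with `chain` and `draw` indices and one column per
#' monitored parameter, plus a JSON-compatible diagnostics attribute written
#' alongside as `<path>.diag.json`.
#'
#' @param fit A `"takeover_fit"`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_draws <- function(fit, path) {
  chains <- lapply(seq_along(fit$samples), function(ch) {
    m <- as.matrix(fit$samples[[ch]])
    data.frame(chain = ch, draw = seq_len(nrow(m)), m, check.names = FALSE)
  })
  utils::write.csv(do.call(rbind, chains), path, row.names = FALSE)
  diag <- list(model = fit$model, max_rhat = fit$diagnostics$max_rhat,
               min_ess = fit$diagnostics$min_ess, converged = fit$converged)
  writeLines(sprintf(
    '{"model": "%s", "max_rhat": %s, "min_ess": %s, "converged": %s}',
    diag$model,
    if (is.na(diag$max_rhat)) "null" else format(diag$max_rhat),
    format(diag$min_ess), if (diag$converged) "true" else "false"),
    paste0(path, ".diag.json"))
  invisible(path)
}
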