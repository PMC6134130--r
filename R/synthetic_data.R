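#' Noise specification for pseudo-experimental sampling
#'
#' Multiplicative lognormal noise with a given coefficient of variation,
#' the standard error structure of relative expression / hormone
#' measurements (positive values, roughly constant CV).
#'
#' @param cv coefficient of variation (default 0.1; 0 = noiseless).
#' @param replicates replicate count per time point (default 3).
#' @param sampling_times ZT sampling grid (default every 4 h).
#' @param seed integer RNG seed.
#' @return list of class \code{noise_spec}.
#' @export
noise_spec <- function(cv = 0.1, replicates = 3,
                       sampling_times = seq(0, 20, by = 4), seed = 1) {
  if (cv < 0) stop("cv must be >= 0", call. = FALSE)
  if (replicates < 1) stop("replicates must be >= 1", call. = FALSE)
  structure(list(cv = cv, replicates = replicates,
                 sampling_times = sampling_times %% 24,
                 seed = as.integer(seed)),
            class = "noise_spec")
}

#' Generate a pseudo-experimental time-course table
#'
#' Entrains the model, samples the listed variables at the noise spec's
#' sampling times and applies multiplicative lognormal noise
#' \code{value * exp(eps)}, \code{eps ~ N(0, sigma)} with
#' \code{sigma = sqrt(log(1 + cv^2))}, independently per replicate.  Fully
#' seeded: the same spec yields the identical table.
#'
#' @param params generating \code{\link{beta_params}} set.
#' @param schedule a \code{\link{feeding_schedule}}.
#' @param variables variables to sample (default: the four clock mRNAs
#'   plus glucose and insulin).
#' @param noise a \code{\link{noise_spec}}.
#' @param ... passed to \code{\link{run_to_limit_cycle}}.
#' @return data.frame (variable, time_h, value, replicate) -- the
#'   time-course table schema used by the calibration module.
#' @export
generate_pseudo_experiment <- function(params,
                                       schedule = feeding_schedule(),
                                       variables = c(bc_clock_mrnas(),
                                                     "glucose", "insulin"),
                                       noise = noise_spec(), ...) {
  traj <- run_to_limit_cycle(params, schedule, ...)
  if (!isTRUE(traj$converged))
    stop("generating parameters do not entrain the model", call. = FALSE)
  ord <- order(traj$times)
  tt <- traj$times[ord]
  sigma <- sqrt(log(1 + noise$cv^2))
  set.seed(noise$seed)
  rows <- list()
  for (v in variables) {
    xx <- .traj_var(traj, v)[ord]
    truth <- stats::approx(tt, xx, xout = noise$sampling_times,
                           rule = 2)$y
    for (r in seq_len(noise$replicates)) {
      eps <- if (noise$cv > 0)
        stats::rnorm(length(truth), 0, sigma) else 0
      rows[[length(rows) + 1]] <- data.frame(
        variable = v, time_h = noise$sampling_times,
        value = truth * exp(eps), replicate = r,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Generate a matched NF/DF table pair
#'
#' Two pseudo-experiments from the same generating parameters: the
#' reference schedule and the same schedule with the feeding window shifted
#' 12 h.  The two tables use distinct, seed-derived noise streams.
#'
#' @inheritParams generate_pseudo_experiment
#' @return list with elements \code{NF} and \code{DF}.
#' @export
generate_condition_pair <- function(params,
                                    schedule = feeding_schedule(),
                                    variables = c(bc_clock_mrnas(),
                                                  "glucose", "insulin"),
                                    noise = noise_spec(), ...) {
  noise_df <- noise
  noise_df$seed <- noise$seed + 1000003L
  df_sched <- feeding_schedule(schedule$food_onset, schedule$food_duration,
                               food_shift = schedule$food_shift + 12)
  list(NF = generate_pseudo_experiment(params, schedule, variables,
                                       noise, ...),
       DF = generate_pseudo_experiment(params, df_sched, variables,
                                       noise_df, ...))
}

#' Validate a time-course table
#'
#' Checks the (variable, time_h, value, replicate) schema, non-negative
#' values and a minimal number of distinct time points per variable.
#'
#' @param table data.frame to validate.
#' @param min_times minimal distinct time points per variable (default 4).
#' @return the table, invisibly; errors describe the violation.
#' @export
validate_timecourse <- function(table, min_times = 4) {
  need <- c("variable", "time_h", "value", "replicate")
  missing <- setdiff(need, names(table))
  if (length(missing))
    stop("table lacks column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  if (any(table$value < 0))
    stop("time-course values must be >= 0", call. = FALSE)
  for (v in unique(table$variable)) {
    nt <- length(unique(table$time_h[table$variable == v]))
    if (nt < min_times)
      stop("variable '", v, "' has only ", nt, " distinct time points",
           call. = FALSE)
  }
  invisible(table)
}
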