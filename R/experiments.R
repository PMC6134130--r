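#' Ablation reference quantities
#'
#' The architecture ablations replace a rhythmic signal by its temporal
#' mean.  The SCN-cue mean is known in closed form; the mean \emph{Exo}
#' transcription rate for the no-clock ablation is computed over the
#' entrained physiological NF cycle and cached here.
#'
#' @param params a \code{\link{beta_params}} set.
#' @param schedule the reference (NF) feeding schedule.
#' @param ... passed to \code{\link{run_to_limit_cycle}}.
#' @return list with \code{exo_const} (mean Exo transcription rate, per h)
#'   and the reference trajectory used to compute it.
#' @export
ablation_reference <- function(params, schedule = feeding_schedule(), ...) {
  ref <- run_to_limit_cycle(params, schedule,
                            architecture = "physiological", ...)
  if (!isTRUE(ref$converged))
    stop("physiological reference run did not entrain", call. = FALSE)
  pb <- .traj_var(ref, "BMAL1_prot")
  exo_tx <- params$v_me * hill_activation(pb, params$K_be, params$n_be)
  list(exo_const = mean(exo_tx), reference = ref)
}

#' Run one experimental condition end-to-end
#'
#' Entrains the model under the given architecture and feeding shift and
#' computes the downstream phase and metabolic summaries.  For the
#' \code{no_clock} architecture the constant \emph{Exo} transcription rate
#' is taken from the physiological NF run (pass a precomputed
#' \code{exo_const} to avoid recomputation in scans).
#'
#' @param params a \code{\link{beta_params}} set.
#' @param architecture \code{"physiological"}, \code{"no_central_clock"} or
#'   \code{"no_clock"}.
#' @param food_shift feeding-window shift in hours (0 = NF, 12 = DF).
#' @param schedule base schedule before the shift is applied.
#' @param exo_const cached mean Exo transcription (required only for
#'   \code{no_clock}; computed on the fly if NULL).
#' @param ... passed to \code{\link{run_to_limit_cycle}}.
#' @return list: \code{trajectory}, \code{phase} (a
#'   \code{\link{phase_report}}, NULL if not entrained),
#'   \code{decomposition}, \code{anticipation}, \code{entrained}.
#' @export
run_condition <- function(params, architecture = "physiological",
                          food_shift = 0,
                          schedule = feeding_schedule(),
                          exo_const = NULL, ...) {
  arch <- match.arg(architecture,
                    c("physiological", "no_central_clock", "no_clock"))
  if (arch == "no_clock" && is.null(exo_const))
    exo_const <- ablation_reference(params, schedule, ...)$exo_const
  sched <- feeding_schedule(schedule$food_onset, schedule$food_duration,
                            food_shift = schedule$food_shift + food_shift)
  traj <- run_to_limit_cycle(params, sched, architecture = arch,
                             exo_const = if (is.null(exo_const)) 0
                                         else exo_const, ...)
  entrained <- isTRUE(traj$converged)
  list(trajectory = traj,
       phase = if (entrained) phase_report(traj) else NULL,
       decomposition = if (entrained) decompose_secretion(traj) else NULL,
       anticipation = if (entrained)
         anticipation_index(traj, sched) else NULL,
       entrained = entrained,
       architecture = arch, food_shift = food_shift)
}

#' Scan the strength of the SCN-driven cue
#'
#' For each value of \code{cneur} on the grid, entrains the model under NF
#' and DF and records the DF-vs-NF circular shift of \emph{Per} and
#' \emph{Bmal1} mRNA and the differential shift statistic.
#'
#' @param params base parameter set (its \code{cneur} is overridden).
#' @param grid cneur values (default 0 to 1.55 in steps of 0.05).
#' @param ... passed to \code{\link{run_to_limit_cycle}}.
#' @return data.frame (cneur, entrained, shift_per_h, shift_bmal1_h,
#'   differential_shift_h); the base set's own cneur is recorded in the
#'   \code{default_cneur} attribute.
#' @export
cneur_scan <- function(params, grid = seq(0, 1.55, by = 0.05), ...) {
  rows <- lapply(grid, function(cn) {
    p <- params
    p$cneur <- cn
    class(p) <- "beta_params"
    nf <- run_condition(p, food_shift = 0, ...)
    df <- run_condition(p, food_shift = 12, ...)
    if (!nf$entrained || !df$entrained)
      return(data.frame(cneur = cn, entrained = FALSE,
                        shift_per_h = NA_real_, shift_bmal1_h = NA_real_,
                        differential_shift_h = NA_real_))
    sh <- condition_shift(nf$phase, df$phase)
    data.frame(
      cneur = cn, entrained = TRUE,
      shift_per_h = sh$shift_h[sh$variable == "per_mRNA"],
      shift_bmal1_h = sh$shift_h[sh$variable == "bmal1_mRNA"],
      differential_shift_h = differential_shift(nf$phase, df$phase))
  })
  out <- do.call(rbind, rows)
  attr(out, "default_cneur") <- params$cneur
  out
}

#' Scan small feeding-schedule shifts
#'
#' For each shift \eqn{\Delta} the model is entrained and compared with the
#' unshifted (NF) reference: differential clock shift and insulin amplitude
#' ratio.
#'
#' @param params a \code{\link{beta_params}} set.
#' @param shifts vector of feeding shifts in hours (default -4..4).
#' @param ... passed to \code{\link{run_to_limit_cycle}}.
#' @return data.frame (shift_h, entrained, differential_shift_h,
#'   insulin_amp_ratio).
#' @export
small_shift_scan <- function(params, shifts = seq(-4, 4, by = 1), ...) {
  nf <- run_condition(params, food_shift = 0, ...)
  if (!nf$entrained) stop("reference NF run did not entrain", call. = FALSE)
  rows <- lapply(shifts, function(dl) {
    run <- run_condition(params, food_shift = dl, ...)
    if (!run$entrained)
      return(data.frame(shift_h = dl, entrained = FALSE,
                        differential_shift_h = NA_real_,
                        insulin_amp_ratio = NA_real_))
    data.frame(
      shift_h = dl, entrained = TRUE,
      differential_shift_h = differential_shift(nf$phase, run$phase),
      insulin_amp_ratio = amplitude_change(nf$trajectory, run$trajectory,
                                           "insulin"))
  })
  do.call(rbind, rows)
}

#' One-at-a-time parameter sensitivity of the differential shift
#'
#' Scans each named parameter over a fold range (multiplicative, log-spaced)
#' and records whether the differential-phase-shift property
#' (shift(Per) - shift(Bmal1) > 0) survives.
#'
#' @param params base parameter set.
#' @param param_names parameters to scan.
#' @param fold_range length-2 multiplicative range (default c(0.5, 2)).
#' @param n_points points per parameter (default 9, log-spaced).
#' @param ... passed to \code{\link{run_to_limit_cycle}}.
#' @return data.frame (parameter, factor, value, entrained, shift_per_h,
#'   shift_bmal1_h, property_holds) plus attribute
#'   \code{property_fraction}.
#' @export
parameter_sensitivity <- function(params, param_names,
                                  fold_range = c(0.5, 2), n_points = 9,
                                  ...) {
  stopifnot(all(param_names %in% names(params)))
  factors <- exp(seq(log(fold_range[1]), log(fold_range[2]),
                     length.out = n_points))
  rows <- list()
  for (pn in param_names) {
    for (f in factors) {
      p <- params
      p[[pn]] <- params[[pn]] * f
      class(p) <- "beta_params"
      row <- data.frame(parameter = pn, factor = f, value = p[[pn]],
                        entrained = FALSE, shift_per_h = NA_real_,
                        shift_bmal1_h = NA_real_, property_holds = NA,
                        stringsAsFactors = FALSE)
      ok <- tryCatch({
        nf <- run_condition(p, food_shift = 0, ...)
        df <- run_condition(p, food_shift = 12, ...)
        nf$entrained && df$entrained
      }, error = function(e) FALSE)
      if (ok) {
        sh <- condition_shift(nf$phase, df$phase)
        row$entrained <- TRUE
        row$shift_per_h <- sh$shift_h[sh$variable == "per_mRNA"]
        row$shift_bmal1_h <- sh$shift_h[sh$variable == "bmal1_mRNA"]
        row$property_holds <- row$shift_per_h - row$shift_bmal1_h > 0
      }
      rows[[length(rows) + 1]] <- row
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "property_fraction") <-
    mean(out$property_holds[out$entrained], na.rm = TRUE)
  out
}

#' Re-entrainment time after a feeding-schedule switch
#'
#' Entrains the model under NF, switches the feeding window by
#' \code{switch_shift} hours (default 12, NF to DF), and counts the number
#' of full 24 h cycles until the trajectory matches the final DF limit
#' cycle within tolerance.  Reported both over all model variables and over
#' the metabolic block only (glucose, insulin), since a clockless
#' metabolic module adapts essentially immediately while the local clock
#' has inertia.
#'
#' @param params a \code{\link{beta_params}} set.
#' @param architecture model architecture (ablation signals taken from the
#'   physiological NF run where needed).
#' @param switch_shift feeding shift applied at the switch (h).
#' @param max_cycles give up after this many post-switch cycles.
#' @param tol normalised sup-distance tolerance (default 1e-3).
#' @param ... passed to \code{\link{run_to_limit_cycle}} /
#'   \code{\link{integrate_model}}.
#' @return list: \code{cycles_all} and \code{cycles_metabolic} (integer,
#'   \code{Inf} if > max_cycles), plus the post-switch trajectory.
#' @export
adaptation_time <- function(params, architecture = "physiological",
                            switch_shift = 12, max_cycles = 100,
                            tol = 1e-3, ...) {
  arch <- match.arg(architecture,
                    c("physiological", "no_central_clock", "no_clock"))
  exo_const <- if (arch == "no_clock")
    ablation_reference(params, ...)$exo_const else 0

  pre <- run_to_limit_cycle(params, feeding_schedule(),
                            architecture = arch, exo_const = exo_const, ...)
  if (!isTRUE(pre$converged))
    stop("pre-switch run did not entrain", call. = FALSE)
  target <- run_to_limit_cycle(params,
                               feeding_schedule(food_shift = switch_shift),
                               architecture = arch, exo_const = exo_const,
                               init = pre$end_state, ...)
  if (!isTRUE(target$converged))
    stop("post-switch run did not entrain", call. = FALSE)

  post <- integrate_model(params, feeding_schedule(food_shift = switch_shift),
                          t_span = c(0, 24 * max_cycles),
                          init = pre$end_state,
                          architecture = arch, exo_const = exo_const,
                          dt = pre$dt, ...)
  n_per <- round(24 / pre$dt)
  tgt_order <- order(target$times)   # target cycle on ZT 0..24-dt grid
  tgt <- target$states[tgt_order, , drop = FALSE]

  first_match <- function(cols) {
    for (k in seq_len(max_cycles)) {
      idx <- ((k - 1) * n_per + 1):(k * n_per)
      d <- .cycle_distance(post$states[idx, cols, drop = FALSE],
                           tgt[, cols, drop = FALSE])
      if (d < tol) return(k - 1L)   # cycles elapsed before lock
    }
    Inf
  }
  list(cycles_all = first_match(bc_model_vars()),
       cycles_metabolic = first_match(c("glucose", "insulin")),
       post_switch = post)
}
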