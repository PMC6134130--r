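#' Integrate the full model
#'
#' Stiff adaptive integration (via \code{deSolve::lsoda} on the compiled
#' right-hand side) of the 15-equation system, resampled on a uniform grid.
#'
#' @param params a \code{\link{beta_params}} set.
#' @param schedule a \code{\link{feeding_schedule}}.
#' @param t_span numeric length-2, start/end time in hours (end - start
#'   >= 24 unless \code{allow_short = TRUE}).
#' @param init named initial state (defaults to \code{\link{bc_init_state}}).
#' @param architecture,exo_const,food_constant see \code{\link{model_rhs}}.
#' @param dt output grid step (h), default 0.05.
#' @param rtol,atol solver tolerances.
#' @param allow_short permit spans shorter than one forcing period.
#' @return object of class \code{beta_trajectory}: list with \code{times},
#'   \code{states} (matrix, one column per variable, plus the secretion
#'   gates \code{fglu}/\code{fexo}), and the run metadata.
#' @export
integrate_model <- function(params, schedule, t_span,
                            init = bc_init_state(),
                            architecture = "physiological",
                            exo_const = 0, food_constant = FALSE,
                            dt = 0.05, rtol = 1e-8, atol = 1e-10,
                            allow_short = FALSE) {
  validate_params(params)
  stopifnot(length(t_span) == 2, t_span[2] > t_span[1])
  if (!allow_short && diff(t_span) < 24)
    stop("t_span must cover at least one 24 h cycle", call. = FALSE)
  if (length(init) != 15 || any(init < 0) || any(!is.finite(init)))
    stop("init must be 15 non-negative finite values", call. = FALSE)

  parms <- .bc_parms_vector(params, schedule, architecture,
                            exo_const = exo_const,
                            food_constant = food_constant)
  times <- seq(t_span[1], t_span[2], by = dt)
  y0 <- setNames(as.numeric(init), bc_state_names())
  out <- deSolve::lsoda(y = y0, times = times, func = "bc_derivs",
                        parms = parms, dllname = "betaclock",
                        initfunc = "bc_initmod", nout = 3,
                        outnames = c("fglu", "fexo", "food_signal"),
                        rtol = rtol, atol = atol, maxsteps = 50000)
  if (attr(out, "istate")[1] < 0 || any(!is.finite(out)))
    stop("integration failed near t = ",
         signif(max(out[stats::complete.cases(out), 1]), 6), " h",
         call. = FALSE)
  traj <- list(times = out[, 1],
               states = out[, -1, drop = FALSE],
               params = params, schedule = schedule,
               architecture = architecture, exo_const = exo_const,
               dt = dt, converged = NA, n_transient_cycles = NA_integer_)
  class(traj) <- "beta_trajectory"
  traj
}

#' Default initial state
#'
#' All variables start at 0.1 (documented, fixed starting point; the
#' transient is discarded by \code{\link{run_to_limit_cycle}}).
#'
#' @return named numeric vector of length 15.
#' @export
bc_init_state <- function() {
  setNames(rep(0.1, 15), bc_state_names())
}

# normalised cycle-to-cycle sup distance between two state matrices
.cycle_distance <- function(a, b) {
  scale <- pmax(apply(b, 2, max) - apply(b, 2, min),
                abs(colMeans(b)), 1e-6)
  max(apply(abs(a - b), 2, max) / scale)
}

#' Integrate to the entrained limit cycle
#'
#' Runs the model cycle-by-cycle from the fixed initial state until the
#' trajectory is 24 h-periodic (normalised cycle-to-cycle sup distance
#' below \code{tol}), then returns one converged cycle sampled on
#' [0, 24) in ZT.  Never silently returns an unconverged run: inspect the
#' \code{converged} flag.
#'
#' @inheritParams integrate_model
#' @param max_cycles give up after this many 24 h cycles (default 200).
#' @param tol periodicity tolerance (default 1e-3).
#' @param init initial state; defaults to \code{\link{bc_init_state}}.
#' @return a \code{beta_trajectory} covering ZT 0-24 with fields
#'   \code{converged} (logical), \code{n_transient_cycles}, and
#'   \code{end_state} (the state at the end of the returned cycle, a
#'   clean restart point).
#' @export
run_to_limit_cycle <- function(params, schedule,
                               architecture = "physiological",
                               exo_const = 0, food_constant = FALSE,
                               init = bc_init_state(),
                               max_cycles = 200, tol = 1e-3,
                               dt = 0.05, rtol = 1e-8, atol = 1e-10) {
  validate_params(params)
  parms <- .bc_parms_vector(params, schedule, architecture,
                            exo_const = exo_const,
                            food_constant = food_constant)
  chunk <- 8L                      # cycles integrated per solver call
  n_per_cycle <- round(24 / dt)
  y0 <- setNames(as.numeric(init), bc_state_names())
  prev_cycle <- NULL
  end_state <- NULL
  cycles_done <- 0L
  converged <- FALSE
  last_states <- NULL
  last_times <- NULL

  while (cycles_done < max_cycles && !converged) {
    n_cyc <- min(chunk, max_cycles - cycles_done)
    times <- seq(0, 24 * n_cyc, by = dt) + 24 * cycles_done
    out <- deSolve::lsoda(y = y0, times = times, func = "bc_derivs",
                          parms = parms, dllname = "betaclock",
                          initfunc = "bc_initmod", nout = 3,
                          outnames = c("fglu", "fexo", "food_signal"),
                          rtol = rtol, atol = atol, maxsteps = 50000)
    if (attr(out, "istate")[1] < 0 || any(!is.finite(out)))
      stop("integration failed during entrainment", call. = FALSE)
    states <- out[, -1, drop = FALSE]
    for (k in seq_len(n_cyc)) {
      idx <- ((k - 1) * n_per_cycle + 1):(k * n_per_cycle)
      cyc <- states[idx, , drop = FALSE]
      if (!is.null(prev_cycle) &&
          .cycle_distance(prev_cycle, cyc) < tol) {
        converged <- TRUE
        last_states <- cyc
        last_times <- (out[idx, 1] - 24 * (cycles_done + k - 1))
        end_state <- states[k * n_per_cycle + 1, seq_len(15)]
        cycles_done <- cycles_done + k
        break
      }
      prev_cycle <- cyc
    }
    if (!converged) {
      cycles_done <- cycles_done + n_cyc
      y0 <- states[nrow(states), seq_len(15)]
      end_state <- y0
      last_states <- states[(nrow(states) - n_per_cycle + 1):nrow(states), ,
                            drop = FALSE]
      last_times <- out[(nrow(out) - n_per_cycle + 1):nrow(out), 1] -
        24 * (cycles_done - 1)
    }
  }

  traj <- list(times = last_times %% 24,
               states = last_states,
               end_state = setNames(as.numeric(end_state),
                                    bc_state_names()),
               params = params, schedule = schedule,
               architecture = architecture, exo_const = exo_const,
               dt = dt, converged = converged,
               n_transient_cycles = cycles_done)
  class(traj) <- "beta_trajectory"
  traj
}

#' @export
print.beta_trajectory <- function(x, ...) {
  cat(sprintf(
    "beta_trajectory: %d samples, t in [%.2f, %.2f] h, architecture %s\n",
    length(x$times), min(x$times), max(x$times), x$architecture))
  if (!is.na(x$converged))
    cat(sprintf("  entrainment: converged = %s after %d cycle(s)\n",
                x$converged, x$n_transient_cycles))
  invisible(x)
}

#' Tidy long-format view of a trajectory
#'
#' @param x a \code{beta_trajectory}.
#' @param row.names,optional unused (S3 signature).
#' @param condition optional condition label column.
#' @param ... unused.
#' @return data.frame with columns time_h, variable, value (and condition).
#' @export
as.data.frame.beta_trajectory <- function(x, row.names = NULL,
                                          optional = FALSE,
                                          condition = NULL, ...) {
  vars <- colnames(x$states)
  d <- data.frame(
    time_h = rep(x$times, times = length(vars)),
    variable = rep(vars, each = length(x$times)),
    value = as.vector(x$states),
    stringsAsFactors = FALSE)
  if (!is.null(condition)) d$condition <- condition
  d
}

# extract one variable's series from a trajectory
.traj_var <- function(traj, variable) {
  if (!variable %in% colnames(traj$states))
    stop("unknown variable: ", variable, call. = FALSE)
  traj$states[, variable]
}
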