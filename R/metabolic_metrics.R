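#' Decompose insulin secretion into its two gates
#'
#' Evaluates the glucose gate \code{f_glu}, the clock gate \code{f_exo} and
#' the secretion flux \code{k_i * f_glu * f_exo} pointwise along an
#' entrained cycle.
#'
#' @param traj an entrained \code{beta_trajectory}.
#' @param params parameter set used for the run (defaults to the one stored
#'   in the trajectory).
#' @return list of class \code{secretion_decomposition} with \code{times},
#'   \code{f_glu}, \code{f_exo}, \code{secretion}, \code{insulin},
#'   \code{glucose}.
#' @export
decompose_secretion <- function(traj, params = traj$params) {
  fg <- f_glu(.traj_var(traj, "glucose"), params)
  fe <- f_exo(.traj_var(traj, "exo_prot"), params)
  out <- list(times = traj$times,
              f_glu = fg, f_exo = fe,
              secretion = params$k_i * fg * fe,
              insulin = .traj_var(traj, "insulin"),
              glucose = .traj_var(traj, "glucose"),
              d_i = params$d_i)
  class(out) <- "secretion_decomposition"
  out
}

#' Coincidence index of the two secretion gates
#'
#' Normalised overlap of the glucose and clock gates over one cycle:
#' \deqn{CI = \frac{\oint f_{glu} f_{exo}\,dt}
#'   {\sqrt{\oint f_{glu}^2\,dt\; \oint f_{exo}^2\,dt}}}
#' By Cauchy-Schwarz \eqn{CI \in [0, 1]}, with 1 iff the two gates are
#' proportional.  High values mean glucose availability and exocytosis
#' capacity peak together (efficient secretion); misalignment lowers it.
#'
#' @param decomp a \code{\link{decompose_secretion}} result.
#' @return value in [0, 1].
#' @export
coincidence_index <- function(decomp) {
  fg <- decomp$f_glu
  fe <- decomp$f_exo
  e_g <- sum(fg^2)
  e_e <- sum(fe^2)
  if (e_g <= 0 || e_e <= 0)
    stop("zero-energy gate signal: coincidence index undefined",
         call. = FALSE)
  sum(fg * fe) / sqrt(e_g * e_e)
}

#' Food-anticipation index and slope rupture
#'
#' Quantifies the food-anticipatory insulin rise: the insulin slope is
#' averaged over a window before food onset (\code{pre_slope}) and after it
#' (\code{post_slope}).  The anticipation index is the pre-onset rise as a
#' fraction of the insulin cycle amplitude
#' (\code{pre_slope * window_h / amplitude}).  A slope rupture -- slow
#' anticipatory rise followed by a much steeper post-meal rise -- is
#' declared when \code{pre_slope > theta_pre * amplitude / 24} and
#' \code{post_slope > slope_ratio * pre_slope}.
#'
#' @param traj an entrained \code{beta_trajectory}.
#' @param schedule feeding schedule of the run (defaults to the stored one).
#' @param window_h averaging window before/after onset (h), default 3.
#' @param theta_pre minimal pre-onset slope, as amplitude fractions per
#'   24 h (default 0.5, i.e. the anticipatory rise must climb at least
#'   ~6\% of the cycle amplitude over a 3 h window).
#' @param slope_ratio required post/pre slope ratio for a rupture
#'   (default 2).
#' @return list of class \code{anticipation_report}: \code{pre_slope},
#'   \code{post_slope}, \code{anticipation_index},
#'   \code{rupture_detected}.
#' @export
anticipation_index <- function(traj, schedule = traj$schedule,
                               window_h = 3, theta_pre = 0.5,
                               slope_ratio = 2) {
  ins <- .traj_var(traj, "insulin")
  t <- traj$times
  onset <- (schedule$food_onset + schedule$food_shift) %% 24
  amp <- max(ins) - min(ins)
  if (amp <= 0) amp <- .Machine$double.eps

  # circular positions relative to onset
  rel <- .circ_signed(t - onset)
  dins <- .bc_cyclic_gradient(ins, traj$dt)
  pre <- rel >= -window_h & rel < 0
  post <- rel >= 0 & rel < window_h
  pre_slope <- mean(dins[pre])
  post_slope <- mean(dins[post])

  rupture <- (pre_slope > theta_pre * amp / 24) &&
    (post_slope > slope_ratio * pre_slope)
  out <- list(pre_slope = pre_slope, post_slope = post_slope,
              anticipation_index = pre_slope * window_h / amp,
              rupture_detected = rupture,
              window_h = window_h, theta_pre = theta_pre,
              slope_ratio = slope_ratio)
  class(out) <- "anticipation_report"
  out
}

# centered finite-difference derivative of a cyclic series
.bc_cyclic_gradient <- function(x, dt) {
  n <- length(x)
  (x[c(2:n, 1)] - x[c(n, 1:(n - 1))]) / (2 * dt)
}

#' Metabolic-syndrome summary of a condition pair
#'
#' Peak and mean insulin and glucose per condition plus their DF/NF-style
#' ratios.  Hypoinsulinemia shows as an insulin ratio < 1, hyperglycemia
#' as a glucose ratio > 1.
#'
#' @param traj_a reference condition (conventionally NF).
#' @param traj_b comparison condition (conventionally DF).
#' @return data.frame with one row per quantity: condition a and b values
#'   and ratio b/a.
#' @export
syndrome_report <- function(traj_a, traj_b) {
  one <- function(traj, var, fun) fun(.traj_var(traj, var))
  qty <- expand.grid(stat = c("peak", "mean"),
                     variable = c("insulin", "glucose"),
                     stringsAsFactors = FALSE)
  rows <- mapply(function(stat, var) {
    fun <- if (stat == "peak") max else mean
    a <- one(traj_a, var, fun)
    b <- one(traj_b, var, fun)
    data.frame(quantity = paste(var, stat, sep = "_"),
               value_a = a, value_b = b, ratio = b / a,
               stringsAsFactors = FALSE)
  }, qty$stat, qty$variable, SIMPLIFY = FALSE)
  do.call(rbind, rows)
}
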