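#' Peak phase of a variable on the entrained cycle
#'
#' Argmax over one 24 h cycle, refined by quadratic interpolation through
#' the three samples bracketing the grid maximum (circular indexing), and
#' returned modulo 24 in ZT hours.
#'
#' @param traj an entrained \code{beta_trajectory} covering one cycle.
#' @param variable state variable name.
#' @return peak phase in [0, 24).
#' @export
peak_phase <- function(traj, variable) {
  x <- .traj_var(traj, variable)
  t <- traj$times
  if ((max(x) - min(x)) < 1e-9)
    stop("flat signal: peak phase of '", variable, "' is undefined",
         call. = FALSE)
  n <- length(x)
  i <- which.max(x)
  im <- if (i == 1) n else i - 1
  ip <- if (i == n) 1 else i + 1
  y1 <- x[im]; y2 <- x[i]; y3 <- x[ip]
  denom <- y1 - 2 * y2 + y3
  offset <- if (abs(denom) < .Machine$double.eps * max(abs(c(y1, y2, y3))))
    0 else 0.5 * (y1 - y3) / denom
  offset <- max(min(offset, 0.5), -0.5)
  (t[i] + offset * traj$dt) %% 24
}

#' Peak-to-trough amplitude
#'
#' @inheritParams peak_phase
#' @param half if TRUE return the half-amplitude (max-min)/2.
#' @return amplitude (a.u.).
#' @export
cycle_amplitude <- function(traj, variable, half = FALSE) {
  x <- .traj_var(traj, variable)
  a <- max(x) - min(x)
  if (half) a / 2 else a
}

#' Minimal circular phase shift between two phases
#'
#' Distance on the 24 h circle from \code{phase_a} to \code{phase_b}:
#' magnitude \code{min(|d|, 24 - |d|)} in [0, 12] h with a direction tag,
#' where \code{d = phase_b - phase_a (mod 24)}.  Positive representative
#' (in (-12, 12]) = delay, negative = advance; exactly 12 h is tagged
#' \code{"antiphase"}.
#'
#' @param phase_a,phase_b phases in hours (interpreted modulo 24).
#' @return list with \code{shift} (h, in [0, 12]), \code{direction}
#'   (\code{"delay"}, \code{"advance"}, \code{"antiphase"} or
#'   \code{"none"}), and \code{signed} (the representative in (-12, 12]).
#' @examples
#' circular_shift(3, 14.63)   # 11.63 h delay
#' circular_shift(20, 4)      # 8 h delay
#' @export
circular_shift <- function(phase_a, phase_b) {
  if (is.na(phase_a) || is.na(phase_b))
    return(list(shift = NA_real_, direction = NA_character_,
                signed = NA_real_))
  d <- .circ_signed(phase_b - phase_a)
  mag <- abs(d)
  dir <- if (mag == 0) "none"
         else if (mag == 12) "antiphase"
         else if (d > 0) "delay" else "advance"
  list(shift = mag, direction = dir, signed = d)
}

#' Phase report for an entrained trajectory
#'
#' Peak phase and peak-to-trough amplitude of every requested variable.
#'
#' @param traj an entrained \code{beta_trajectory}.
#' @param variables variable names (default: the 13 model variables).
#' @return data.frame (variable, peak_phase_h, amplitude) of class
#'   \code{phase_report}.
#' @export
phase_report <- function(traj, variables = bc_model_vars()) {
  if (!isTRUE(traj$converged))
    warning("phase report computed on a non-entrained trajectory")
  rep <- data.frame(
    variable = variables,
    peak_phase_h = vapply(variables, function(v)
      tryCatch(peak_phase(traj, v), error = function(e) NA_real_), 0),
    amplitude = vapply(variables, function(v) cycle_amplitude(traj, v), 0),
    row.names = NULL, stringsAsFactors = FALSE)
  class(rep) <- c("phase_report", "data.frame")
  rep
}

.report_phase <- function(report, variable) {
  i <- match(variable, report$variable)
  if (is.na(i)) stop("variable '", variable, "' not in phase report",
                     call. = FALSE)
  report$peak_phase_h[i]
}

#' Between-condition phase shifts
#'
#' Circular peak-phase shift of every shared variable between two phase
#' reports (e.g. NF vs DF).
#'
#' @param report_a,report_b \code{\link{phase_report}} objects.
#' @return data.frame (variable, shift_h, direction, signed_h).
#' @export
condition_shift <- function(report_a, report_b) {
  vars <- intersect(report_a$variable, report_b$variable)
  rows <- lapply(vars, function(v) {
    s <- circular_shift(.report_phase(report_a, v), .report_phase(report_b, v))
    data.frame(variable = v, shift_h = s$shift, direction = s$direction,
               signed_h = s$signed, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Differential phase shift of the clock arms
#'
#' Signed circular phase difference Bmal1 - Per (representative in
#' (-12, 12]) computed in each condition; the statistic is the condition-A
#' value minus the condition-B value, wrapped back to (-12, 12].  It is 0
#' when the whole clock rotates rigidly (e.g. a uniform 12 h shift) and
#' grows when the positive and negative arms shift by different amounts.
#'
#' @param report_a,report_b phase reports of the two conditions
#'   (conventionally NF and DF).
#' @param var_pos,var_neg variables representing the positive and negative
#'   clock arms (defaults \code{bmal1_mRNA}, \code{per_mRNA}).
#' @return signed differential shift in hours, in (-12, 12].
#' @export
differential_shift <- function(report_a, report_b,
                               var_pos = "bmal1_mRNA",
                               var_neg = "per_mRNA") {
  da <- .circ_signed(.report_phase(report_a, var_pos) -
                     .report_phase(report_a, var_neg))
  db <- .circ_signed(.report_phase(report_b, var_pos) -
                     .report_phase(report_b, var_neg))
  .circ_signed(da - db)
}

#' Amplitude ratio between two conditions
#'
#' Peak-to-trough amplitude of \code{variable} in \code{traj_b} divided by
#' that in \code{traj_a}.
#'
#' @param traj_a,traj_b entrained trajectories.
#' @param variable state variable name.
#' @return dimensionless ratio.
#' @export
amplitude_change <- function(traj_a, traj_b, variable) {
  a <- cycle_amplitude(traj_a, variable)
  if (a <= 0) stop("zero amplitude in reference condition", call. = FALSE)
  cycle_amplitude(traj_b, variable) / a
}

#' Write a phase report (with optional shifts) as tidy CSV
#'
#' @param report a \code{\link{phase_report}}.
#' @param path output file.
#' @param condition condition label stored in the CSV.
#' @export
write_phase_report <- function(report, path, condition = "NF") {
  d <- as.data.frame(report)
  d$condition <- condition
  utils::write.csv(d[, c("variable", "condition", "peak_phase_h",
                         "amplitude")], path, row.names = FALSE)
  invisible(path)
}
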