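#' Feeding / lighting schedule
#'
#' Describes the zeitgeber geometry of a run in Zeitgeber Time (ZT; ZT0 =
#' lights-on, ZT12 = lights-off, 24 h period).  The light-dark cycle is fixed
#' at 12:12; the feeding window is free.  The default window (onset ZT12,
#' duration 12 h) is nocturnal feeding (NF), the normal active phase of a
#' nocturnal rodent.  \code{food_shift = 12} turns it into daytime feeding
#' (DF, feeding restricted to the rest phase); arbitrary shifts model
#' advances/delays of the eating schedule.  The SCN cue never moves with the
#' feeding schedule.
#'
#' @param food_onset ZT hour at which the feeding window opens (default 12).
#' @param food_duration window length in hours, in (0, 24); default 12.
#' @param food_shift shift applied to the window onset, hours (interpreted
#'   modulo 24); 0 = NF, 12 = DF.
#' @return a list of class \code{feeding_schedule}.
#' @examples
#' nf <- feeding_schedule()
#' df <- feeding_schedule(food_shift = 12)
#' @export
feeding_schedule <- function(food_onset = 12, food_duration = 12,
                             food_shift = 0) {
  if (!is.numeric(food_duration) || food_duration <= 0 || food_duration >= 24)
    stop("food_duration must lie in (0, 24)", call. = FALSE)
  s <- list(food_onset = food_onset %% 24,
            food_duration = food_duration,
            food_shift = food_shift %% 24)
  class(s) <- "feeding_schedule"
  s
}

#' @export
print.feeding_schedule <- function(x, ...) {
  onset <- (x$food_onset + x$food_shift) %% 24
  cat(sprintf(
    "feeding schedule: window ZT%.2f-ZT%.2f (duration %.1f h, shift %+.1f h)\n",
    onset, (onset + x$food_duration) %% 24, x$food_duration, x$food_shift))
  invisible(x)
}

# signed circular hour difference, representative in (-12, 12]
.circ_signed <- function(d) {
  d <- d %% 24
  ifelse(d > 12, d - 24, d)
}

#' Feeding drive signal
#'
#' Smooth square-ish pulse that is ~1 inside the feeding window and ~0
#' outside, with logistic edges of width \code{edge} hours.  This is the
#' drive feeding the two-variable food-intake cascade
#' (\code{\link{food_intake_rhs}}); it stands for the burst of pellet intake
#' during the feeding window.
#'
#' @param t time (h); vectorised.
#' @param schedule a \code{\link{feeding_schedule}}.
#' @param edge edge smoothing width in hours (default 0.25).
#' @return drive level in [0, 1].
#' @export
food_drive <- function(t, schedule, edge = 0.25) {
  onset <- (schedule$food_onset + schedule$food_shift) %% 24
  half <- schedule$food_duration / 2
  centre <- onset + half
  delta <- abs(.circ_signed(t - centre))
  1 / (1 + exp(-(half - delta) / edge))
}

#' Two-variable food-intake subsystem
#'
#' Right-hand side of the relaxation cascade drive -> fast eating activity
#' (\code{food_act}) -> slow satiety pool (\code{food_sat}).  The nutrient
#' signal that raises blood glucose in the full model is
#' \code{max(food_act - food_sat, 0)}: a front-loaded intake pulse that
#' peaks shortly after the feeding window opens and then declines as the
#' satiety pool fills, mirroring the burst of pellet intake at dark onset.
#' With a constant unit drive both state components converge to 1.
#'
#' @param t time (h).
#' @param food_state numeric length-2 vector \code{c(food_act, food_sat)}.
#' @param schedule a \code{\link{feeding_schedule}}.
#' @param params a \code{\link{beta_params}} set (uses \code{k_fa},
#'   \code{k_fo}, \code{food_edge}).
#' @return length-2 derivative vector.
#' @export
food_intake_rhs <- function(t, food_state, schedule, params) {
  stopifnot(length(food_state) == 2)
  drive <- food_drive(t, schedule, edge = params$food_edge)
  c(params$k_fa * (drive - food_state[[1]]),
    params$k_fo * (food_state[[1]] - food_state[[2]]))
}

#' SCN-driven neural cue
#'
#' Clipped-cosine waveform: a half-cosine bump peaking in the light phase
#' (default ZT6), zero through the dark half-cycle, scaled by the coupling
#' strength \code{cneur} (temporal mean \code{cneur / pi}).  The cue is
#' locked to the light-dark cycle: it is identical under any feeding
#' schedule.  With \code{cneur = 0} the signal is identically zero (its own
#' mean), i.e. the cue is absent.
#'
#' @param t time (h); vectorised.
#' @param cneur coupling strength (>= 0).
#' @param scn_peak ZT hour of the cue peak, default 6.
#' @return cue level >= 0.
#' @export
scn_cue <- function(t, cneur, scn_peak = 6) {
  if (cneur < 0) stop("cneur must be >= 0", call. = FALSE)
  cneur * pmax(0, cos(2 * pi * (t - scn_peak) / 24))
}
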