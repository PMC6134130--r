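# State layout of the coupled model.  The first 9 entries are the clock
# components (mRNA + protein for Bmal1, Per, Cry, Rev-Erb plus the PER-CRY
# complex); then the metabolic block; the last 2 are the food-intake
# subsystem.

#' State variable names
#'
#' \code{bc_state_names()} returns all 15 integrated variables (13 model
#' variables + the 2-equation food-intake subsystem); \code{bc_clock_vars()}
#' the 9 clock components; \code{bc_clock_mrnas()} the four clock-gene mRNAs
#' whose phases are tracked in the feeding-inversion experiments.
#'
#' @return character vector of variable names.
#' @export
bc_state_names <- function() {
  c("bmal1_mRNA", "BMAL1_prot", "per_mRNA", "PER_prot",
    "cry_mRNA", "CRY_prot", "percry_complex", "rev_mRNA", "REV_prot",
    "glucose", "insulin", "exo_mRNA", "exo_prot",
    "food_act", "food_sat")
}

#' @rdname bc_state_names
#' @export
bc_model_vars <- function() bc_state_names()[1:13]

#' @rdname bc_state_names
#' @export
bc_clock_vars <- function() bc_state_names()[1:9]

#' @rdname bc_state_names
#' @export
bc_clock_mrnas <- function() c("bmal1_mRNA", "per_mRNA", "cry_mRNA",
                               "rev_mRNA")

#' Hill regulatory functions
#'
#' Building blocks of all regulation in the model:
#' \code{hill_activation(x, K, n) = x^n / (K^n + x^n)} and
#' \code{hill_repression(x, K, n) = K^n / (K^n + x^n)}.  They are
#' complementary (sum to 1 at equal arguments) and map onto [0, 1].
#'
#' @param x regulator concentration (>= 0); vectorised.
#' @param K half-saturation threshold (> 0).
#' @param n Hill exponent (>= 1).
#' @return fraction in [0, 1].
#' @examples
#' hill_activation(3, 1, 2)   # 9/10
#' hill_repression(0, 1, 4)   # 1
#' @export
hill_activation <- function(x, K, n) {
  if (K <= 0) stop("Hill threshold K must be > 0", call. = FALSE)
  if (n < 1) stop("Hill exponent n must be >= 1", call. = FALSE)
  if (any(x < 0)) stop("regulator concentration must be >= 0", call. = FALSE)
  xn <- x^n
  xn / (K^n + xn)
}

#' @rdname hill_activation
#' @export
hill_repression <- function(x, K, n) {
  if (K <= 0) stop("Hill threshold K must be > 0", call. = FALSE)
  if (n < 1) stop("Hill exponent n must be >= 1", call. = FALSE)
  if (any(x < 0)) stop("regulator concentration must be >= 0", call. = FALSE)
  Kn <- K^n
  Kn / (Kn + x^n)
}

#' Secretion gating functions
#'
#' The two multiplicative gates of insulin secretion: \code{f_glu} is the
#' saturating effect of blood glucose, \code{f_exo} the effect of the
#' clock-controlled exocytosis machinery (EXO protein).  High secretion
#' requires both to be high simultaneously (coincidence mechanism).
#'
#' @param glucose blood glucose level (>= 0); vectorised.
#' @param exo_prot EXO protein level (>= 0); vectorised.
#' @param params a \code{\link{beta_params}} set.
#' @return fraction in [0, 1].
#' @export
f_glu <- function(glucose, params) {
  if (any(glucose < 0)) stop("glucose must be >= 0", call. = FALSE)
  hill_activation(glucose, params$K_ig, params$n_ig)
}

#' @rdname f_glu
#' @export
f_exo <- function(exo_prot, params) {
  if (any(exo_prot < 0)) stop("exo_prot must be >= 0", call. = FALSE)
  hill_activation(exo_prot, params$K_ie, params$n_ie)
}

#' Insulin balance equation
#'
#' Rate of change of blood insulin: secretion \code{k_i * f_glu * f_exo}
#' minus first-order clearance \code{d_i * insulin}.
#'
#' @param insulin insulin level (>= 0).
#' @param f_glu_val,f_exo_val gate values in [0, 1].
#' @param params a \code{\link{beta_params}} set (uses \code{k_i},
#'   \code{d_i}).
#' @return secretion - clearance (a.u. per hour).
#' @export
insulin_derivative <- function(insulin, f_glu_val, f_exo_val, params) {
  params$k_i * f_glu_val * f_exo_val - params$d_i * insulin
}

#' Model right-hand side (reference R implementation)
#'
#' Full derivative of the 15-variable system (13 model variables + 2
#' food-intake variables) at time \code{t}.  Integration uses an identical
#' compiled version of this function; the R version is the readable
#' reference and is cross-checked against the compiled one in the test
#' suite.
#'
#' Network logic: BMAL1 protein activates \emph{Per}, \emph{Cry},
#' \emph{Rev-Erb} and \emph{Exo} transcription; the PER-CRY complex blocks
#' the action of BMAL1 on the clock genes; REV-ERB protein represses
#' \emph{Bmal1} transcription.  The glucose cue adds to \emph{Per}
#' transcription (strength \code{c_glu}); the SCN cue adds to \emph{Rev-Erb}
#' transcription (strength \code{cneur}).  Food intake raises glucose;
#' insulin promotes glucose uptake; every species decays linearly.
#'
#' @param t time (h).
#' @param state named numeric vector in \code{\link{bc_state_names}} order.
#' @param params a \code{\link{beta_params}} set.
#' @param schedule a \code{\link{feeding_schedule}}.
#' @param architecture \code{"physiological"} (default),
#'   \code{"no_central_clock"} (SCN cue replaced by its temporal mean) or
#'   \code{"no_clock"} (\emph{Exo} transcription replaced by the constant
#'   \code{exo_const}).
#' @param exo_const constant \emph{Exo} transcription rate for the
#'   \code{no_clock} ablation.
#' @param food_constant if TRUE the feeding drive is replaced by its
#'   temporal mean (used for free-running-clock analyses).
#' @return named derivative vector, same layout as \code{state}.
#' @export
model_rhs <- function(t, state, params, schedule,
                      architecture = "physiological", exo_const = 0,
                      food_constant = FALSE) {
  arch <- match.arg(architecture,
                    c("physiological", "no_central_clock", "no_clock"))
  if (any(!is.finite(state)))
    stop("non-finite state passed to model_rhs", call. = FALSE)
  s <- setNames(as.numeric(state), bc_state_names())
  p <- params

  rep_cp <- hill_repression(s[["percry_complex"]], p$K_pc, p$n_pc)
  scn_in <- if (arch == "no_central_clock") p$cneur / pi
            else scn_cue(t, p$cneur, p$scn_peak)
  drive <- if (food_constant) schedule$food_duration / 24
           else food_drive(t, schedule, edge = p$food_edge)

  fglu <- f_glu(s[["glucose"]], p)
  fexo <- f_exo(s[["exo_prot"]], p)
  exo_tx <- if (arch == "no_clock") exo_const
            else p$v_me * hill_activation(s[["BMAL1_prot"]], p$K_be, p$n_be)

  d <- c(
    bmal1_mRNA = p$v_mb * hill_repression(s[["REV_prot"]], p$K_rb, p$n_rb) -
      p$d_mb * s[["bmal1_mRNA"]],
    BMAL1_prot = p$k_pb * s[["bmal1_mRNA"]] - p$d_pb * s[["BMAL1_prot"]],
    per_mRNA = p$v_mp * hill_activation(s[["BMAL1_prot"]], p$K_bp, p$n_bp) *
      rep_cp + p$c_glu * hill_activation(s[["glucose"]], p$K_gp, p$n_gp) -
      p$d_mp * s[["per_mRNA"]],
    PER_prot = p$k_pp * s[["per_mRNA"]] -
      p$k_ass * s[["PER_prot"]] * s[["CRY_prot"]] +
      p$k_dis * s[["percry_complex"]] - p$d_pp * s[["PER_prot"]],
    cry_mRNA = p$v_mc * hill_activation(s[["BMAL1_prot"]], p$K_bc, p$n_bc) *
      rep_cp - p$d_mc * s[["cry_mRNA"]],
    CRY_prot = p$k_pcr * s[["cry_mRNA"]] -
      p$k_ass * s[["PER_prot"]] * s[["CRY_prot"]] +
      p$k_dis * s[["percry_complex"]] - p$d_pcr * s[["CRY_prot"]],
    percry_complex = p$k_ass * s[["PER_prot"]] * s[["CRY_prot"]] -
      p$k_dis * s[["percry_complex"]] - p$d_cp * s[["percry_complex"]],
    rev_mRNA = p$v_mr * hill_activation(s[["BMAL1_prot"]], p$K_br, p$n_br) *
      rep_cp + scn_in - p$d_mr * s[["rev_mRNA"]],
    REV_prot = p$k_pr * s[["rev_mRNA"]] - p$d_pr * s[["REV_prot"]],
    glucose = p$v_gb +
      p$k_fg * max(s[["food_act"]] - s[["food_sat"]], 0) -
      p$d_g * s[["glucose"]] -
      p$k_gi * s[["insulin"]] * s[["glucose"]],
    insulin = insulin_derivative(s[["insulin"]], fglu, fexo, p),
    exo_mRNA = exo_tx - p$d_me * s[["exo_mRNA"]],
    exo_prot = p$k_pe * s[["exo_mRNA"]] - p$d_pe * s[["exo_prot"]],
    food_act = p$k_fa * (drive - s[["food_act"]]),
    food_sat = p$k_fo * (s[["food_act"]] - s[["food_sat"]])
  )
  d
}
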