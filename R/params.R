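#' @useDynLib betaclock
#' @importFrom stats setNames
NULL

# Order of the numeric parameter vector handed to the compiled right-hand
# side.  Must match the #define block in src/betaclock.c.
.bc_param_order <- c(
  "v_mb", "d_mb", "k_pb", "d_pb",
  "v_mp", "K_bp", "n_bp", "c_glu", "K_gp", "n_gp", "d_mp",
  "k_pp", "d_pp",
  "v_mc", "K_bc", "n_bc", "d_mc",
  "k_pcr", "d_pcr",
  "k_ass", "k_dis", "d_cp",
  "K_pc", "n_pc",
  "v_mr", "K_br", "n_br", "d_mr", "cneur",
  "k_pr", "d_pr",
  "K_rb", "n_rb",
  "v_gb", "k_fg", "d_g", "k_gi",
  "k_i", "K_ig", "n_ig", "K_ie", "n_ie", "d_i",
  "v_me", "K_be", "n_be", "d_me",
  "k_pe", "d_pe",
  "k_fa", "k_fo",
  "scn_peak", "food_edge"
)

# Parameters that are Hill exponents (must be >= 1); everything else in the
# kinetic block must be > 0 except the coupling strengths, which may be 0.
.bc_hill_exponents <- c("n_bp", "n_gp", "n_pc", "n_br", "n_rb",
                        "n_ig", "n_ie", "n_be", "n_bc")
.bc_nonneg_ok <- c("c_glu", "cneur")

#' Reference model parameters
#'
#' Returns the full kinetic parameter set of the coupled beta-cell
#' clock / glucose-insulin model.  Time is measured in hours, concentrations
#' are dimensionless (relative-expression scale).  The set was calibrated so
#' that the autonomous clock free-runs with a circadian period close to but
#' not equal to 24 h, entrains stably to a 12 h nocturnal feeding window plus
#' a light-phase SCN cue, and reproduces the qualitative phenotype of
#' nocturnal rodents: \emph{Per} expression tracking food intake, \emph{Bmal1}
#' in near antiphase, insulin secretion gated by the coincidence of glucose
#' and clock-driven exocytosis capacity.
#'
#' Parameter groups:
#' \describe{
#'   \item{v_m*, d_m*}{maximal transcription and mRNA degradation rates
#'     (per hour) for \emph{Bmal1}, \emph{Per}, \emph{Cry}, \emph{Rev-Erb}
#'     and the exocytosis factor \emph{Exo}.}
#'   \item{k_p*, d_p*}{translation and protein degradation rates.}
#'   \item{K_*, n_*}{Hill thresholds and exponents of the regulatory
#'     functions (BMAL1 activation, PER-CRY and REV-ERB repression, glucose
#'     sensing).}
#'   \item{k_ass, k_dis, d_cp}{PER-CRY complex association, dissociation and
#'     degradation.}
#'   \item{c_glu}{coupling strength of the glucose cue onto \emph{Per}
#'     transcription (the food zeitgeber input to the clock).}
#'   \item{cneur}{coupling strength of the SCN-driven neural cue onto
#'     \emph{Rev-Erb} transcription (the light zeitgeber input); 0 removes
#'     the cue entirely.}
#'   \item{v_gb, k_fg, d_g, k_gi}{basal glucose production, feeding-driven
#'     glucose input, first-order glucose clearance, insulin-dependent
#'     glucose uptake.}
#'   \item{k_i, d_i}{maximal insulin secretion rate and insulin clearance.}
#'   \item{K_ig, n_ig / K_ie, n_ie}{thresholds and exponents of the two
#'     secretion gates \code{f_glu} (glucose) and \code{f_exo} (EXO
#'     protein).}
#'   \item{k_fa, k_fo}{rate constants of the two-variable food-intake
#'     relaxation cascade (drive -> activator -> intake signal).}
#'   \item{scn_peak}{ZT hour at which the SCN cue peaks (default ZT6,
#'     mid-light phase).}
#'   \item{food_edge}{smoothing width (h) of the feeding-pulse edges.}
#' }
#'
#' @param ... named overrides of individual parameters.
#' @return a named list of class \code{beta_params}.
#' @examples
#' p <- beta_params()
#' p$cneur
#' p2 <- beta_params(cneur = 0)   # remove the SCN cue
#' @export
beta_params <- function(...) {
  p <- .bc_reference_params()
  override <- list(...)
  if (length(override)) {
    if (is.null(names(override)) || any(names(override) == ""))
      stop("all parameter overrides must be named", call. = FALSE)
    unknown <- setdiff(names(override), names(p))
    if (length(unknown))
      stop("unknown parameter(s): ", paste(unknown, collapse = ", "),
           call. = FALSE)
    p[names(override)] <- lapply(override, as.numeric)
  }
  class(p) <- "beta_params"
  validate_params(p)
  p
}

# The calibrated reference set (see the methods vignette for how it was
# obtained).  Values in per-hour units; concentrations dimensionless.
.bc_reference_params <- function() {
  list(
    v_mb = 0.409676,  d_mb = 0.204838, k_pb = 0.409676, d_pb = 0.204838,
    v_mp = 0.573547,  K_bp = 2,        n_bp = 4,        c_glu = 1.41811,
    K_gp = 7.58945,   n_gp = 4,        d_mp = 0.204838,
    k_pp = 0.181203,  d_pp = 0.236352,
    v_mc = 0.819353,  K_bc = 2,        n_bc = 4,        d_mc = 0.204838,
    k_pcr = 0.307257, d_pcr = 0.189081,
    k_ass = 0.236352, k_dis = 0.0590879, d_cp = 0.110297,
    K_pc = 1,         n_pc = 6,
    v_mr = 11.66,     K_br = 2,        n_br = 6,        d_mr = 0.14575,
    cneur = 1.4336,
    k_pr = 0.014575,  d_pr = 0.14575,
    K_rb = 2,         n_rb = 10,
    v_gb = 2.83339,   k_fg = 11.3,     d_g = 0.321479,  k_gi = 0.824824,
    k_i = 2,          K_ig = 7.58945,  n_ig = 4,        K_ie = 1.26491,
    n_ie = 4,         d_i = 0.5,
    v_me = 0.399445,  K_be = 2,        n_be = 4,        d_me = 0.199723,
    k_pe = 0.199723,  d_pe = 0.199723,
    k_fa = 3,         k_fo = 0.5,
    scn_peak = 6,     food_edge = 0.25
  )
}

#' Validate a model parameter set
#'
#' Checks completeness, positivity of rates and thresholds, Hill exponents
#' \eqn{\ge 1}, and non-negative coupling strengths.
#'
#' @param p a \code{beta_params} list (or plain named list).
#' @return the validated parameter list, invisibly.
#' @export
validate_params <- function(p) {
  missing <- setdiff(.bc_param_order, names(p))
  if (length(missing))
    stop("missing parameter(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  unknown <- setdiff(names(p), .bc_param_order)
  if (length(unknown))
    stop("unknown parameter(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  vals <- unlist(p[.bc_param_order])
  if (any(!is.finite(vals)))
    stop("non-finite parameter value(s)", call. = FALSE)
  hexp <- vals[.bc_hill_exponents]
  if (any(hexp < 1))
    stop("Hill exponent(s) < 1: ",
         paste(names(hexp)[hexp < 1], collapse = ", "), call. = FALSE)
  nonneg <- vals[.bc_nonneg_ok]
  if (any(nonneg < 0))
    stop("negative coupling strength(s): ",
         paste(names(nonneg)[nonneg < 0], collapse = ", "), call. = FALSE)
  strict <- setdiff(.bc_param_order,
                    c(.bc_hill_exponents, .bc_nonneg_ok, "scn_peak"))
  sv <- vals[strict]
  if (any(sv <= 0))
    stop("non-positive rate/threshold parameter(s): ",
         paste(names(sv)[sv <= 0], collapse = ", "), call. = FALSE)
  if (p$scn_peak < 0 || p$scn_peak >= 24)
    stop("scn_peak must lie in [0, 24)", call. = FALSE)
  invisible(p)
}

#' @export
print.beta_params <- function(x, ...) {
  cat("beta-cell clock model parameters (", length(.bc_param_order),
      " kinetic constants)\n", sep = "")
  v <- unlist(x[.bc_param_order])
  print(round(v, 5))
  invisible(x)
}

# Flatten parameters + schedule + architecture switches into the numeric
# vector consumed by the compiled rhs.  `exo_const` is the cached mean Exo
# transcription rate used by the no-clock ablation.
.bc_parms_vector <- function(params, schedule,
                             architecture = "physiological",
                             exo_const = 0,
                             food_constant = FALSE) {
  arch <- match.arg(architecture,
                    c("physiological", "no_central_clock", "no_clock"))
  base <- unlist(params[.bc_param_order])
  onset <- (schedule$food_onset + schedule$food_shift) %% 24
  c(base,
    food_onset = onset,
    food_dur = schedule$food_duration,
    scn_mode = as.numeric(identical(arch, "no_central_clock")),
    exo_mode = as.numeric(identical(arch, "no_clock")),
    exo_const = exo_const,
    food_mode = as.numeric(food_constant))
}
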