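#' Read / write model parameters
#'
#' Parameters are stored as a flat key-value mapping in YAML or JSON
#' (chosen by file extension).  Loading validates the set: unknown or
#' missing keys and out-of-range values are rejected with a named error,
#' so a save/load round trip is lossless.
#'
#' @param path file path ending in .yaml/.yml or .json.
#' @param params a \code{\link{beta_params}} set (for saving).
#' @return \code{load_params}: a validated \code{beta_params} list.
#' @export
load_params <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  vals <- switch(.bc_ext(path),
                 yaml = yaml::read_yaml(path),
                 json = jsonlite::read_json(path, simplifyVector = TRUE))
  vals <- as.list(vals)
  missing <- setdiff(.bc_param_order, names(vals))
  if (length(missing))
    stop("parameter file lacks required key(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  do.call(beta_params, vals)
}

#' @rdname load_params
#' @export
save_params <- function(params, path) {
  validate_params(params)
  vals <- lapply(params[.bc_param_order], as.numeric)
  switch(.bc_ext(path),
         yaml = yaml::write_yaml(vals, path, precision = 15),
         json = jsonlite::write_json(vals, path, auto_unbox = TRUE,
                                     digits = NA))
  invisible(path)
}

.bc_ext <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("yaml", "yml")) return("yaml")
  if (ext == "json") return("json")
  stop("unsupported parameter file extension: .", ext,
       " (use .yaml or .json)", call. = FALSE)
}

#' Write a trajectory as tidy CSV
#'
#' Long format (time_h, variable, value, condition), directly consumable
#' by any stats environment.
#'
#' @param traj a \code{beta_trajectory}.
#' @param path output CSV path.
#' @param condition condition label.
#' @export
write_trajectory <- function(traj, path, condition = "NF") {
  utils::write.csv(as.data.frame(traj, condition = condition), path,
                   row.names = FALSE)
  invisible(path)
}

# run manifest: config echo + package version + seed
.bc_write_manifest <- function(out_dir, config, seed = NA) {
  manifest <- list(
    package = "betaclock",
    version = as.character(utils::packageVersion("betaclock")),
    seed = seed,
    config = config)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
}

#' Command-line entry point
#'
#' Thin argv-level interface over the package functions, suitable for
#' wrapping in an Rscript.  Subcommands:
#' \describe{
#'   \item{simulate}{\code{--params FILE --shift H --out DIR}: entrain and
#'     write the trajectory CSV + manifest.}
#'   \item{experiment}{\code{--name inversion --params FILE --out DIR}:
#'     NF/DF inversion with phase-report and summary output.}
#'   \item{synth}{\code{--params FILE --cv X --seed N --out DIR}: write a
#'     synthetic time-course table.}
#'   \item{fit}{\code{--params FILE --table FILE --free a,b,c --out DIR}:
#'     refit the named parameters to a time-course table.}
#' }
#'
#' @param argv character vector of arguments (as from
#'   \code{commandArgs(trailingOnly = TRUE)}).
#' @return integer exit code (0 success, 2 usage error), invisibly.
#' @export
betaclock_cli <- function(argv) {
  usage <- function(msg) {
    message("betaclock: ", msg)
    message("usage: betaclock {simulate|experiment|synth|fit} [--params FILE]",
            " [--shift H] [--name NAME] [--table FILE] [--free a,b,c]",
            " [--cv X] [--seed N] --out DIR")
    invisible(2L)
  }
  if (!length(argv)) return(usage("missing subcommand"))
  cmd <- argv[1]
  opts <- .bc_parse_opts(argv[-1])
  if (is.character(opts)) return(usage(opts))
  if (is.null(opts$out)) return(usage("--out is required"))
  if (!cmd %in% c("simulate", "experiment", "synth", "fit"))
    return(usage(paste("unknown subcommand:", cmd)))

  dir.create(opts$out, recursive = TRUE, showWarnings = FALSE)
  params <- if (is.null(opts$params)) beta_params()
            else load_params(opts$params)
  shift <- if (is.null(opts$shift)) 0 else as.numeric(opts$shift)
  seed <- if (is.null(opts$seed)) 1L else as.integer(opts$seed)

  status <- tryCatch({
    if (cmd == "simulate") {
      traj <- run_to_limit_cycle(params, feeding_schedule(food_shift = shift))
      if (!isTRUE(traj$converged)) stop("model did not entrain")
      write_trajectory(traj, file.path(opts$out, "trajectory.csv"),
                       condition = if (shift == 12) "DF" else "NF")
    } else if (cmd == "experiment") {
      name <- if (is.null(opts$name)) "inversion" else opts$name
      if (name != "inversion")
        stop("unsupported experiment: ", name,
             " (use the R functions for scans)")
      nf <- run_condition(params, food_shift = 0)
      df <- run_condition(params, food_shift = 12)
      if (!nf$entrained || !df$entrained) stop("model did not entrain")
      write_phase_report(nf$phase, file.path(opts$out, "phase_NF.csv"), "NF")
      write_phase_report(df$phase, file.path(opts$out, "phase_DF.csv"), "DF")
      utils::write.csv(condition_shift(nf$phase, df$phase),
                       file.path(opts$out, "shifts.csv"), row.names = FALSE)
      summarise <- function(run, cond) {
        tr <- run$trajectory
        list(condition = cond,
             insulin_peak = max(tr$states[, "insulin"]),
             insulin_mean = mean(tr$states[, "insulin"]),
             glucose_peak = max(tr$states[, "glucose"]),
             glucose_mean = mean(tr$states[, "glucose"]),
             coincidence_index = coincidence_index(run$decomposition),
             anticipation_index =
               run$anticipation$anticipation_index,
             rupture_detected = run$anticipation$rupture_detected)
      }
      jsonlite::write_json(list(NF = summarise(nf, "NF"),
                                DF = summarise(df, "DF")),
                           file.path(opts$out, "summary.json"),
                           auto_unbox = TRUE, digits = NA)
    } else if (cmd == "synth") {
      cv <- if (is.null(opts$cv)) 0.1 else as.numeric(opts$cv)
      tab <- generate_pseudo_experiment(
        params, noise = noise_spec(cv = cv, seed = seed))
      utils::write.csv(tab, file.path(opts$out, "timecourse.csv"),
                       row.names = FALSE)
    } else if (cmd == "fit") {
      if (is.null(opts$table)) stop("--table is required for fit")
      if (is.null(opts$free)) stop("--free is required for fit")
      tab <- utils::read.csv(opts$table, stringsAsFactors = FALSE)
      validate_timecourse(tab)
      free <- strsplit(opts$free, ",")[[1]]
      rec <- recover_parameters(tab, params, free, seed = seed,
                                rtol = 1e-6, atol = 1e-8)
      save_params(rec$fitted_params,
                  file.path(opts$out, "fitted_params.yaml"))
      jsonlite::write_json(
        list(cost = rec$fit$value, evals = rec$fit$evals,
             converged = rec$fit$converged,
             relative_error = as.list(rec$relative_error)),
        file.path(opts$out, "fit.json"), auto_unbox = TRUE, digits = NA)
    }
    0L
  }, error = function(e) {
    message("betaclock ", cmd, " failed: ", conditionMessage(e))
    1L
  })
  if (status == 0L)
    .bc_write_manifest(opts$out, c(list(command = cmd), opts), seed = seed)
  invisible(status)
}

.bc_parse_opts <- function(args) {
  opts <- list()
  i <- 1
  while (i <= length(args)) {
    a <- args[i]
    if (!startsWith(a, "--")) return(paste("unexpected argument:", a))
    key <- substring(a, 3)
    if (i + 1 > length(args)) return(paste("missing value for", a))
    opts[[key]] <- args[i + 1]
    i <- i + 2
  }
  opts
}
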