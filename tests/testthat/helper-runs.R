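# shared entrained runs, computed once per test session (loose-but-adequate
# tolerances keep the suite fast; metric tests that need tighter solver
# settings run their own integrations)

bc_ref_runs <- local({
  cache <- new.env(parent = emptyenv())
  function(what = c("NF", "DF", "ncc_NF", "ncc_DF", "noclock_NF",
                    "noclock_DF", "exo_const")) {
    what <- match.arg(what)
    if (!is.null(cache[[what]])) return(cache[[what]])
    p <- beta_params()
    if (is.null(cache$exo_const))
      cache$exo_const <- ablation_reference(p)$exo_const
    val <- switch(what,
      NF = run_condition(p, "physiological", 0),
      DF = run_condition(p, "physiological", 12),
      ncc_NF = run_condition(p, "no_central_clock", 0),
      ncc_DF = run_condition(p, "no_central_clock", 12),
      noclock_NF = run_condition(p, "no_clock", 0,
                                 exo_const = cache$exo_const),
      noclock_DF = run_condition(p, "no_clock", 12,
                                 exo_const = cache$exo_const),
      exo_const = cache$exo_const)
    cache[[what]] <- val
    val
  }
})

# synthetic two-harmonic periodic signal used by phase-metric oracle tests
bc_two_harmonic <- function(t, a1, phi1, a2, phi2, mean = 2) {
  w <- 2 * pi / 24
  mean + a1 * cos(w * (t - phi1)) + a2 * cos(2 * w * (t - phi2))
}

# wrap a plain (times, matrix) pair into a minimal trajectory object
bc_fake_traj <- function(times, states, dt = diff(times[1:2])) {
  structure(list(times = times, states = states, dt = dt,
                 converged = TRUE, n_transient_cycles = 0L,
                 schedule = feeding_schedule(),
                 params = beta_params(), architecture = "physiological"),
            class = "beta_trajectory")
}
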