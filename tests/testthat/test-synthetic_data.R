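test_that("noiseless tables reproduce the model curve exactly at sample
           times", {
  p <- beta_params()
  tab <- generate_pseudo_experiment(p, noise = noise_spec(cv = 0),
                                    variables = c("per_mRNA", "insulin"))
  validate_timecourse(tab)
  traj <- bc_ref_runs("NF")$trajectory
  ord <- order(traj$times)
  for (v in unique(tab$variable)) {
    truth <- approx(traj$times[ord], traj$states[ord, v],
                    xout = unique(tab$time_h))$y
    got <- tab$value[tab$variable == v & tab$replicate == 1]
    expect_equal(got, truth, tolerance = 1e-9)
  }
  # replicates are identical when cv = 0
  expect_equal(tab$value[tab$replicate == 2],
               tab$value[tab$replicate == 1])
})

test_that("noise is seeded, reproducible, and has the nominal CV", {
  p <- beta_params()
  n1 <- noise_spec(cv = 0.1, seed = 7)
  t1 <- generate_pseudo_experiment(p, noise = n1,
                                   variables = "per_mRNA")
  t2 <- generate_pseudo_experiment(p, noise = n1,
                                   variables = "per_mRNA")
  expect_identical(t1, t2)
  t3 <- generate_pseudo_experiment(p, noise = noise_spec(cv = 0.1,
                                                         seed = 8),
                                   variables = "per_mRNA")
  expect_false(identical(t1$value, t3$value))

  # Monte-Carlo: empirical per-point CV within 15% of nominal
  big <- generate_pseudo_experiment(
    p, noise = noise_spec(cv = 0.1, replicates = 200, seed = 3),
    variables = "per_mRNA")
  cvs <- tapply(big$value, big$time_h, function(v) sd(v) / mean(v))
  expect_lt(abs(mean(cvs) - 0.1) / 0.1, 0.15)
})

test_that("condition pairs mirror the 12 h symmetry when the SCN cue is
           absent", {
  p <- beta_params(cneur = 0)
  pair <- generate_condition_pair(p, noise = noise_spec(cv = 0),
                                  variables = c("per_mRNA", "glucose"),
                                  tol = 1e-5)
  validate_timecourse(pair$NF)
  validate_timecourse(pair$DF)
  # DF table equals the NF table sampled 12 h earlier (cv = 0)
  for (v in c("per_mRNA", "glucose")) {
    nf <- pair$NF[pair$NF$variable == v & pair$NF$replicate == 1, ]
    df <- pair$DF[pair$DF$variable == v & pair$DF$replicate == 1, ]
    shifted <- nf$value[match((df$time_h - 12) %% 24, nf$time_h)]
    expect_equal(df$value, shifted, tolerance = 1e-4)
  }
})

test_that("interpolating a noisy table recovers the generating peak phase", {
  # the oracle is the band-limited (2-harmonic) peak of the noiseless
  # curve; the Fourier peak of a sharp asymmetric waveform carries a
  # truncation bias that is bounded separately below
  p <- beta_params()
  traj <- bc_ref_runs("NF")$trajectory
  dense <- seq(0, 23.99, by = 0.01)
  fit_peak <- function(tab, v) {
    f <- fourier_interpolate(tab, v)
    dense[which.max(f$fun(dense))]
  }
  circ <- function(a, b) abs(((a - b) + 12) %% 24 - 12)
  for (v in c("per_mRNA", "bmal1_mRNA")) {
    tab0 <- generate_pseudo_experiment(p, noise = noise_spec(cv = 0),
                                       variables = v,
                                       rtol = 1e-6, atol = 1e-8)
    ref <- fit_peak(tab0, v)
    # truncation bias of the harmonic representation stays modest
    expect_lt(circ(ref, peak_phase(traj, v)), 1.5)
    hits <- 0
    n_seeds <- 20
    for (seed in seq_len(n_seeds)) {
      tab <- generate_pseudo_experiment(
        p, noise = noise_spec(cv = 0.1, seed = seed),
        variables = v, rtol = 1e-6, atol = 1e-8)
      if (circ(fit_peak(tab, v), ref) < 1) hits <- hits + 1
    }
    expect_gte(hits / n_seeds, 0.95)
  }
})

test_that("schema validation catches malformed tables", {
  bad <- data.frame(variable = "x", time_h = 1:3, value = 1)
  expect_error(validate_timecourse(bad), "replicate")
  neg <- data.frame(variable = "x", time_h = c(0, 6, 12, 18),
                    value = c(1, -1, 1, 1), replicate = 1)
  expect_error(validate_timecourse(neg), ">= 0")
  sparse <- data.frame(variable = "x", time_h = c(0, 8, 16),
                       value = 1, replicate = 1)
  expect_error(validate_timecourse(sparse), "distinct time points")
})
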