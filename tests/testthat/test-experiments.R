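test_that("feeding inversion splits the clock arms in the physiological
           architecture", {
  nf <- bc_ref_runs("NF")
  df <- bc_ref_runs("DF")
  expect_true(nf$entrained && df$entrained)
  sh <- condition_shift(nf$phase, df$phase)
  per <- sh$shift_h[sh$variable == "per_mRNA"]
  bmal <- sh$shift_h[sh$variable == "bmal1_mRNA"]
  expect_gt(per - bmal, 2)
  expect_gt(per, 10.5)

  # the experiment layer adds no physics: metrics recomputed from the
  # stored trajectory reproduce the cached report exactly
  expect_identical(phase_report(nf$trajectory), nf$phase)
  expect_identical(coincidence_index(decompose_secretion(nf$trajectory)),
                   coincidence_index(nf$decomposition))
})

test_that("without a rhythmic SCN cue the whole clock follows food by 12 h", {
  nc_nf <- bc_ref_runs("ncc_NF")
  nc_df <- bc_ref_runs("ncc_DF")
  expect_true(nc_nf$entrained && nc_df$entrained)
  sh <- condition_shift(nc_nf$phase, nc_df$phase)
  clock <- sh$shift_h[sh$variable %in% bc_clock_vars()]
  expect_true(all(abs(clock - 12) < 0.1))
  expect_equal(amplitude_change(nc_nf$trajectory, nc_df$trajectory,
                                "insulin"), 1, tolerance = 0.02)
})

test_that("clockless secretion makes NF and DF metabolically identical", {
  nk_nf <- bc_ref_runs("noclock_NF")
  nk_df <- bc_ref_runs("noclock_DF")
  expect_true(nk_nf$entrained && nk_df$entrained)
  sy <- syndrome_report(nk_nf$trajectory, nk_df$trajectory)
  expect_true(all(abs(sy$ratio - 1) < 0.02))
  # constant f_exo: secretion proportional to f_glu
  d <- nk_nf$decomposition
  expect_lt(diff(range(d$f_exo)), 1e-6)
  expect_equal(d$secretion / d$f_glu,
               rep(d$secretion[1] / d$f_glu[1], length(d$f_glu)),
               tolerance = 1e-8)
})

test_that("small-shift scan: identity at zero, consistency at 12", {
  p <- beta_params()
  ss <- small_shift_scan(p, shifts = c(0, 12), rtol = 1e-6, atol = 1e-8)
  expect_true(all(ss$entrained))
  expect_equal(ss$differential_shift_h[ss$shift_h == 0], 0)
  expect_equal(ss$insulin_amp_ratio[ss$shift_h == 0], 1)
  # delta = 12 reproduces the DF condition
  df <- run_condition(p, food_shift = 12, rtol = 1e-6, atol = 1e-8)
  nf <- run_condition(p, food_shift = 0, rtol = 1e-6, atol = 1e-8)
  expect_equal(ss$differential_shift_h[ss$shift_h == 12],
               differential_shift(nf$phase, df$phase), tolerance = 1e-8)
})

test_that("parameter sensitivity scan: identity factor reproduces baseline
           and the differential-shift property holds there", {
  p <- beta_params()
  sens <- parameter_sensitivity(p, "d_i", fold_range = c(0.8, 1.25),
                                n_points = 3, rtol = 1e-6, atol = 1e-8)
  expect_equal(nrow(sens), 3)
  mid <- sens[abs(sens$factor - 1) < 1e-9, ]
  expect_true(mid$entrained)
  expect_true(mid$property_holds)
  nf <- bc_ref_runs("NF"); df <- bc_ref_runs("DF")
  sh <- condition_shift(nf$phase, df$phase)
  # reference runs use tighter solver settings; phases agree to ~0.01 h
  expect_equal(mid$shift_per_h, sh$shift_h[sh$variable == "per_mRNA"],
               tolerance = 1e-3)
  frac <- attr(sens, "property_fraction")
  expect_gte(frac, 0)
  expect_lte(frac, 1)
})

test_that("adaptation: a null switch costs nothing, a clockless metabolic
           module adapts within a cycle, local clocks have inertia", {
  p <- beta_params()
  null_switch <- adaptation_time(p, "physiological", switch_shift = 0,
                                 rtol = 1e-6, atol = 1e-8)
  expect_identical(null_switch$cycles_all, 0L)

  nk <- adaptation_time(p, "no_clock", rtol = 1e-6, atol = 1e-8)
  expect_lte(nk$cycles_metabolic, 1)

  nc <- adaptation_time(p, "no_central_clock", rtol = 1e-6, atol = 1e-8)
  expect_gte(nc$cycles_all, 2)
})

test_that("cneur scan columns and anchor point", {
  p <- beta_params()
  cs <- cneur_scan(p, grid = c(0, p$cneur), rtol = 1e-6, atol = 1e-8)
  expect_named(cs, c("cneur", "entrained", "shift_per_h", "shift_bmal1_h",
                     "differential_shift_h"))
  expect_true(all(cs$entrained))
  expect_equal(cs$shift_per_h[1], 12, tolerance = 0.05)
  expect_equal(cs$shift_bmal1_h[1], 12, tolerance = 0.05)
  expect_lt(cs$shift_bmal1_h[2], cs$shift_bmal1_h[1] + 0.2)
})
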