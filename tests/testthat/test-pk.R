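test_that("terminal_half_life recovers exact exponentials and guards", {
  t <- c(10, 20, 30, 40, 50)
  p <- plasma_profile(t, 100 * 2^(-t / 30), dose_mg_kg = 1)
  tf <- terminal_half_life(p)
  expect_equal(tf$t_half_h, 0.5, tolerance = 1e-10)
  expect_equal(tf$r_squared, 1, tolerance = 1e-9)

  flat <- plasma_profile(t, rep(5, 5), dose_mg_kg = 1)
  expect_error(terminal_half_life(flat), class = "no_terminal_decline_error")
  lone <- plasma_profile(c(10, 20), c(5, 0), dose_mg_kg = 1,
                         censored = c(FALSE, TRUE))
  expect_error(terminal_half_life(lone), class = "insufficiency_error")
})

test_that("terminal regression on the absorption model recovers the elimination half-life", {
  # absorption t1/2 6 min, elimination t1/2 0.38 h, sampled at the
  # subcutaneous design times, window 30-120 min
  sim <- simulate_plasma_pk(pk_sim_config(t_half_abs_h = 0.1,
                                          t_half_elim_h = 0.38, cv = 0),
                            seed = 1)
  tf <- terminal_half_life(sim$profile, window = c(30, 120))
  expect_lt(abs(tf$t_half_h - 0.38) / 0.38, 0.05)
})

test_that("auc_inf integrates triangles, exponentials and censored zeros", {
  # triangle 0 -> 100 ng/mL over 1 h -> 0 at 2 h: area 100 h*ng/mL
  tri <- plasma_profile(c(60, 120), c(100, 0), dose_mg_kg = 1)
  expect_equal(auc_inf(tri, tail = FALSE)$auc_h_ng_ml, 100)

  # dense pure exponential + tail ~ C0/k
  k <- log(2) / 30  # per min
  t <- seq(1, 150, length.out = 1000)
  pe <- plasma_profile(t, 50 * exp(-k * t), dose_mg_kg = 1, route = "iv")
  a <- auc_inf(pe)
  expect_lt(abs(a$auc_h_ng_ml - 50 / (k * 60)) / (50 / (k * 60)), 0.01)

  # trailing assigned-zero: trapezoid includes the segment to zero and no
  # tail is added in "observed" mode; "exclude" mode extrapolates instead
  t5 <- c(30, 60, 90, 120, 240)
  c5 <- c(80, 40, 20, 10, 0)
  pz <- plasma_profile(t5, c5, dose_mg_kg = 1,
                       censored = c(FALSE, FALSE, FALSE, FALSE, TRUE))
  obs <- auc_inf(pz, "observed")
  expect_equal(obs$auc_tail, 0)
  expect_equal(obs$extrapolated_fraction, 0)
  exc <- auc_inf(pz, "exclude")
  expect_gt(exc$auc_tail, 0)
  expect_equal(exc$auc_observed + 10 / exc$k_per_h, exc$auc_h_ng_ml)
  # the observed 120 -> 240 triangle to zero vs the exponential tail
  expect_equal(obs$auc_observed - exc$auc_observed, (240 - 120) * 10 / 2 / 60)

  zeros <- plasma_profile(c(10, 20), c(0, 0), dose_mg_kg = 1,
                          censored = c(TRUE, TRUE))
  expect_warning(z <- auc_inf(zeros), "all-zero")
  expect_equal(z$auc_h_ng_ml, 0)
  expect_true(z$zero_profile)
})

test_that("AUC is additive over a split at any interior grid point", {
  sim <- simulate_plasma_pk(pk_sim_config(cv = 0, lod_ng_ml = 0), seed = 1)
  p <- sim$profile
  full <- auc_inf(p, tail = FALSE)$auc_h_ng_ml
  for (a_idx in 2:(length(p$time_min) - 1)) {
    a <- p$time_min[a_idx]
    left <- plasma_profile(p$time_min[p$time_min <= a],
                           p$conc_ng_ml[p$time_min <= a], p$dose_mg_kg)
    # shift the right-hand segment so its grid starts at 0 (no re-anchoring)
    right <- plasma_profile(p$time_min[p$time_min >= a] - a,
                            p$conc_ng_ml[p$time_min >= a], p$dose_mg_kg)
    expect_equal(auc_inf(left, tail = FALSE)$auc_h_ng_ml +
                   auc_inf(right, tail = FALSE)$auc_h_ng_ml,
                 full, tolerance = 1e-12)
  }
})

test_that("trapezoid error shrinks ~4x when sampling density doubles", {
  cfg0 <- pk_sim_config(cv = 0, lod_ng_ml = 0)
  exact <- 1000 / 0.73
  err <- vapply(c(200, 400, 800), function(n) {
    cfg <- pk_sim_config(cv = 0, lod_ng_ml = 0,
                         time_min = seq(0.5, 2000, length.out = n))
    abs(auc_inf(simulate_plasma_pk(cfg, 1)$profile)$auc_h_ng_ml - exact)
  }, 0)
  expect_gt(err[1] / err[2], 3)
  expect_gt(err[2] / err[3], 3)
})

test_that("clearance converts units and inverts", {
  expect_equal(round(clearance(1, 1370), 2), 0.73)
  expect_equal(clearance(1, 1e6), 0.001)
  # CL x AUC returns the dose exactly
  auc <- 1370
  expect_equal(clearance(1, auc) * auc / 1000, 1)
  expect_error(clearance(1, 0), class = "division_guard_error")

  # doubling all concentrations halves CL
  sim <- simulate_plasma_pk(pk_sim_config(cv = 0, lod_ng_ml = 0), seed = 1)
  p1 <- sim$profile
  p2 <- plasma_profile(p1$time_min, 2 * p1$conc_ng_ml, p1$dose_mg_kg)
  cl1 <- clearance(p1$dose_mg_kg, auc_inf(p1))
  cl2 <- clearance(p2$dose_mg_kg, auc_inf(p2))
  expect_equal(cl2, cl1 / 2)
})

test_that("pk_nca assembles the three NCA quantities coherently", {
  sim <- simulate_plasma_pk(pk_sim_config(), seed = 3)
  res <- pk_nca(sim$profile, window = c(30, 120))
  expect_s3_class(res, "pk_nca")
  expect_equal(res$cl_L_h_kg,
               sim$profile$dose_mg_kg * 1000 / res$auc_h_ng_ml)
  expect_gte(res$extrapolated_fraction, 0)
  expect_lt(res$extrapolated_fraction, 1)
  expect_output(print(res), "clearance")
})
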