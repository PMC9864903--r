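test_that("human_organ_fraction applies the mass-ratio extrapolation", {
  cu <- suv_curve("liver", c(5, 60), c(2, 0), decay_corrected = FALSE)
  ph <- phantom("male", 73.7, c(liver = 300, blood = 5000, "red marrow" = 1100))
  fc <- human_organ_fraction(cu, ph)
  expect_equal(fc$fraction, c(2 * 300 / 73700, 0))

  # whole-body-sized organ at SUV 1 -> fraction 1
  ph1 <- phantom("male", 73.7, c(body = 73700))
  f1 <- human_organ_fraction(suv_curve("body", 5, 1, decay_corrected = FALSE), ph1)
  expect_equal(f1$fraction, 1)

  # decay-corrected input is a state error, unknown organ an alias error
  expect_error(human_organ_fraction(suv_curve("liver", 5, 1), ph),
               class = "state_error")
  expect_error(human_organ_fraction(
    suv_curve("antenna", 5, 1, decay_corrected = FALSE), ph),
    class = "alias_error")
  # aliasing: dissected "kidney" resolves to phantom "kidneys"
  fk <- human_organ_fraction(
    suv_curve("kidney", 5, 1, decay_corrected = FALSE),
    phantom("male", 73.7, c(kidneys = 299)))
  expect_identical(fk$organ, "kidneys")
})

test_that("residence_time matches closed forms and annotates the tail", {
  lam_h <- log(2) / (ga68$half_life_min / 60)

  # all activity in one organ decaying purely physically: tau = T1/2 / ln 2
  t <- seq(0, 600, by = 5)
  pure <- organ_fraction_curve("organ", t, exp(-lam_h * t / 60))
  rt <- residence_time(pure, ga68)
  expect_equal(rt$tau_h, ga68$half_life_min / 60 / log(2), tolerance = 2e-3)
  expect_false(rt$clamped)

  # piecewise: constant 0.5 over [0, 60 min] then physical decay
  # (trapezoid is exact for the flat part; the curve starts at t = 0 so no
  # zero-anchor is prepended)
  t2 <- c(0, 30, 60)
  flat <- organ_fraction_curve("organ", t2, c(0.5, 0.5, 0.5))
  rt2 <- residence_time(flat, ga68)
  expect_equal(rt2$trapezoid_h, 0.5)
  expect_equal(rt2$tau_h, 0.5 + 0.5 / lam_h, tolerance = 1e-9)
  expect_true(rt2$clamped)  # flat tail is apparent accumulation -> physical decay

  # monotonically increasing kidney-like curve engages the clamp annotation
  t3 <- c(5, 10, 20, 40, 60, 90, 120, 180)
  kid <- organ_fraction_curve("kidneys", t3, 0.1 * (1 - exp(-0.02 * t3)))
  rt3 <- residence_time(kid, ga68)
  expect_true(rt3$clamped)
  expect_match(rt3$note, "accumulation")
  expect_equal(rt3$tail_rate_per_h, lam_h)

  # all-zero curve: tau 0, not an error
  z <- residence_time(organ_fraction_curve("x", t3, rep(0, 8)), ga68)
  expect_equal(z$tau_h, 0)

  # trapezoid stage is exact for piecewise-linear curves
  tpl <- c(0, 10, 30, 60)
  fpl <- c(0, 0.3, 0.1, 0)
  pl <- residence_time(organ_fraction_curve("x", tpl, fpl), ga68)
  expect_equal(pl$trapezoid_h,
               sum(diff(tpl / 60) * (head(fpl, -1) + tail(fpl, -1)) / 2))
})

test_that("residence times respect the physical bound for normalized input", {
  bound <- ga68$half_life_min / 60 / log(2)
  lam <- decay_constant(ga68, "min")
  set.seed(99)
  for (i in 1:20) {
    t <- sort(runif(6, 1, 240))
    # whole-body fraction <= 1 at all times, decaying at least physically
    f <- runif(1, 0.2, 1) * exp(-lam * t) * exp(-runif(1, 0, 0.02) * t)
    rt <- residence_time(organ_fraction_curve("wb", t, f), ga68)
    # trapezoid quadrature can only overshoot by its standard second-order
    # error bound, (lambda * h_max)^2 / 12 relative
    quad_tol <- (lam * max(diff(c(0, t))))^2 / 12
    expect_lte(rt$tau_h, bound * (1 + quad_tol + 1e-9))
  }
})

test_that("marrow blood-volume model is linear in RMBLR and masses", {
  t <- c(5, 30, 60, 120)
  blood <- organ_fraction_curve("blood", t, 0.2 * exp(-0.03 * t))
  ph <- phantom("male", 73.7,
                c(blood = 5000, "red marrow" = 1120, liver = 1800))
  tau_blood <- residence_time(blood, ga68)$tau_h
  m1 <- marrow_residence(blood, ph, ga68, rmblr = 1)
  expect_equal(m1$tau_h, (1120 / 5000) * tau_blood, tolerance = 1e-12)
  m05 <- marrow_residence(blood, ph, ga68, rmblr = 0.5)
  expect_equal(m05$tau_h, 0.5 * m1$tau_h, tolerance = 1e-12)
  expect_equal(marrow_residence(blood, ph, ga68, rmblr = 0)$tau_h, 0)
  # RMBLR 1 with marrow mass = blood mass reproduces the blood tau
  ph_eq <- phantom("male", 73.7, c(blood = 5000, "red marrow" = 5000))
  expect_equal(marrow_residence(blood, ph_eq, ga68)$tau_h, tau_blood,
               tolerance = 1e-12)
  expect_error(marrow_residence(NULL, ph, ga68), class = "dependency_error")
})

test_that("remainder_residence implements both constructions with clamping", {
  bound <- ga68$half_life_min / 60 / log(2)
  expect_equal(remainder_residence(numeric(), ga68), bound)
  expect_equal(remainder_residence(c(a = bound / 2, b = bound / 2), ga68), 0)
  expect_equal(remainder_residence(c(a = 0.4), ga68, "whole_body_curve",
                                   whole_body_tau_h = 0.4), 0)
  expect_warning(
    r <- remainder_residence(c(a = 0.5), ga68, "whole_body_curve",
                             whole_body_tau_h = 0.3), "clamped")
  expect_equal(r, 0)
  expect_error(remainder_residence(c(a = 2 * bound), ga68),
               class = "inconsistency_error")
})

test_that("organ_doses equals a dense matrix-product oracle", {
  # single source/target one-term sum
  sv1 <- svalue_table(data.frame(target = "liver", source = "liver",
                                 s_mGy_per_MBq_h = 0.1))
  d1 <- organ_doses(c(liver = 2), sv1)
  expect_equal(d1$dose_mGy_per_MBq, 0.2)

  # random toy tables vs dense matrix-vector product
  set.seed(7)
  organs <- c("a", "b", "c")
  for (rep in 1:5) {
    S <- matrix(runif(9), 3, 3, dimnames = list(organs, organs))
    tau <- setNames(runif(3), organs)
    ent <- expand.grid(target = organs, source = organs,
                       stringsAsFactors = FALSE)
    ent$s_mGy_per_MBq_h <- S[cbind(ent$target, ent$source)]
    dt <- organ_doses(tau, svalue_table(ent))
    oracle <- as.numeric(S %*% tau)
    expect_equal(setNames(dt$dose_mGy_per_MBq, dt$organ),
                 setNames(oracle, organs)[dt$organ])
    # linearity: doubling all tau doubles every dose
    dt2 <- organ_doses(2 * tau, svalue_table(ent))
    expect_equal(dt2$dose_mGy_per_MBq, 2 * dt$dose_mGy_per_MBq)
  }

  # missing source is a completeness error naming it
  expect_error(organ_doses(c(liver = 1, spleen = 1), sv1), "spleen",
               class = "table_completeness_error")
})

test_that("effective dose applies ICRP-60 conventions and is linear", {
  dm <- read_organ_dose_table(sex = "male")
  em <- effective_dose(dm, icrp60, phantom_m)
  # kidney is the hottest remainder organ and triggers the split rule
  expect_true(em$remainder$split_rule)
  expect_identical(unname(em$remainder$hottest_organ), "kidneys")
  # contributions sum exactly to the effective dose
  expect_equal(sum(em$contributions), em$effective_dose, tolerance = 1e-9)
  # linearity
  e2 <- effective_dose(dm * 3, icrp60, phantom_m)
  expect_equal(e2$effective_dose, 3 * em$effective_dose, tolerance = 1e-12)
  # all-zero doses give zero
  e0 <- effective_dose(setNames(rep(0, length(dm)), names(dm)), icrp60, phantom_m)
  expect_equal(e0$effective_dose, 0)
  # colon split and esophagus surrogate enter as specified
  expect_equal(unname(em$contributions[["colon"]]),
               0.12 * (0.57 * dm[["uli wall"]] + 0.43 * dm[["lli wall"]]))
  expect_equal(unname(em$contributions[["esophagus"]]), 0.05 * dm[["thymus"]])
  # missing named tissue without surrogate is a completeness error
  expect_error(effective_dose(dm[names(dm) != "liver"], icrp60, phantom_m),
               class = "completeness_error")

  # when no remainder organ beats the named tissues the weight is not split
  flat <- setNames(rep(1, length(dm)), names(dm))
  ef <- effective_dose(flat, icrp60, phantom_m)
  expect_false(ef$remainder$split_rule)
  expect_equal(ef$effective_dose, 1)  # weights sum to 1 on a uniform field
})

test_that("end-to-end synthetic chain recovers analytic residence times", {
  sim <- simulate_biodistribution(biodist_kinetics(cv = 0), seed = 1)
  rep <- dosimetry_report(sim$dataset)
  cfg <- sim$truth$config
  al <- organ_aliases()
  for (sex in c("male", "female")) {
    ph <- if (sex == "male") phantom_m else phantom_f
    taus <- rep$per_sex[[sex]]$taus
    for (i in seq_len(nrow(cfg$organs))) {
      org <- cfg$organs$organ[i]
      can <- if (org %in% names(ph$organ_masses)) org else unname(al[org])
      if (is.na(can) || !can %in% names(ph$organ_masses) ||
          can %in% c("blood", "red marrow")) next
      scale <- (cfg$body_weight_g / cfg$organs$mass_g[i]) *
        ph$organ_masses[[can]] / (1000 * ph$body_mass_kg)
      analytic <- scale * sim$truth$decayed_integral_h[[org]]
      expect_lt(abs(taus[[can]] - analytic) / analytic, 0.05)
    }
    # physical bound on the residence-time set
    expect_lte(sum(taus), ga68$half_life_min / 60 / log(2) + 1e-6)
  }
})

test_that("dosimetry_report handles degenerate inputs and is deterministic", {
  # single-organ pure physical decay: all dose mass flows from that organ
  t <- c(5, 10, 20, 40, 60, 90, 120, 180)
  lam <- decay_constant(ga68, "min")
  ph <- phantom("male", 73.7, c(liver = 73700 / 2, blood = 100),
                remainder_organs = "liver")
  # activities engineered so the decay-uncorrected human liver fraction is
  # exp(-lambda t): SUV_A(t) = 2 e^(-lam t) and m_organ/M_body = 1/2
  samples <- data.frame(animal_id = "r1", organ = "liver", time_min = t,
                        activity_MBq = exp(-lam * t) * 5 / 350 * 2,
                        sample_mass_g = 5, group = "baseline")
  inj <- data.frame(animal_id = "r1", injected_MBq = 1, body_weight_g = 350)
  ds <- biodist_dataset(samples, inj, decay_corrected = FALSE)
  sv <- selfdose_svalues(ph, ga68)
  w <- tissue_weights(c(liver = 0.95), 0.05)
  rep1 <- dosimetry_report(ds, phantoms = list(male = ph),
                           svalues = list(male = sv), weights = w)
  tau_liver <- rep1$per_sex$male$taus[["liver"]]
  expect_equal(tau_liver, ga68$half_life_min / 60 / log(2), tolerance = 0.05)
  expect_gt(rep1$per_sex$male$doses$dose_mGy_per_MBq[
    rep1$per_sex$male$doses$organ == "liver"], 0)

  # zero-activity dataset: all-zero report
  samples0 <- samples; samples0$activity_MBq <- 0
  ds0 <- biodist_dataset(samples0, inj, decay_corrected = FALSE)
  rep0 <- dosimetry_report(ds0, phantoms = list(male = ph),
                           svalues = list(male = sv), weights = w)
  expect_equal(rep0$per_sex$male$effective$effective_dose, 0)

  # determinism: rebuilding from the same inputs is identical
  rep2 <- dosimetry_report(ds, phantoms = list(male = ph),
                           svalues = list(male = sv), weights = w)
  expect_identical(rep1$per_sex, rep2$per_sex)
})
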