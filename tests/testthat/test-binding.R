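test_that("specific_binding subtracts, clamps and reports", {
  expect_equal(as.numeric(specific_binding(c(1, 2), c(0.2, 0.5))), c(0.8, 1.5))
  expect_equal(as.numeric(specific_binding(c(1, 1), c(1, 1))), c(0, 0))
  expect_warning(s <- specific_binding(c(1, 0.1), c(0.5, 0.3)), "clamped")
  expect_equal(as.numeric(s), c(0.5, 0))
  expect_identical(attr(s, "n_clamped"), 1L)
  expect_error(specific_binding(1:3, 1:2), class = "alignment_error")

  # noise-free one-site + linear NS: subtraction returns the hyperbola
  sim <- simulate_saturation_assay(assay_sim_config(cv = 0), seed = 1)
  spec <- specific_binding(sim$data$total, sim$data$nonspecific)
  hyper <- sim$truth$bmax * sim$data$conc_nM / (sim$truth$kd_nM + sim$data$conc_nM)
  expect_equal(as.numeric(spec), hyper, tolerance = 1e-12)
})

test_that("saturation_fit recovers noise-free parameters and midpoint", {
  conc <- c(0.3, 1, 3, 10, 30, 100, 300)
  spec <- 5 * conc / (10 + conc)
  fit <- saturation_fit(conc, specific = spec)
  expect_equal(unname(coef(fit)), c(10, 5), tolerance = 1e-6)
  expect_equal(predict(fit, 10), 2.5, tolerance = 1e-6)  # B(Kd) = Bmax/2

  expect_error(saturation_fit(c(1, 2, 3), specific = c(1, 2, 3)),
               class = "validation_error")
})

test_that("saturation_fit agrees with an independent grid-search minimizer", {
  sim <- simulate_saturation_assay(assay_sim_config(cv = 0.1), seed = 11)
  spec <- suppressWarnings(specific_binding(sim$data$total, sim$data$nonspecific))
  fit <- saturation_fit(sim$data$conc_nM, specific = as.numeric(spec))
  oracle <- grid_search_hyperbola(sim$data$conc_nM, as.numeric(spec),
                                  kd_range = c(1, 200))
  expect_lt(abs(fit$kd_nM - oracle[["kd"]]) / oracle[["kd"]], 0.01)
  expect_lt(abs(fit$bmax - oracle[["bmax"]]) / oracle[["bmax"]], 0.01)
})

test_that("saturation_fit is scale-equivariant in the bound values", {
  sim <- simulate_saturation_assay(assay_sim_config(cv = 0.05), seed = 5)
  spec <- as.numeric(specific_binding(sim$data$total, sim$data$nonspecific))
  f1 <- saturation_fit(sim$data$conc_nM, specific = spec)
  f2 <- saturation_fit(sim$data$conc_nM, specific = spec * 7)
  expect_equal(f2$kd_nM, f1$kd_nM, tolerance = 1e-6)
  expect_equal(f2$bmax, f1$bmax * 7, tolerance = 1e-6)
})

test_that("one-step total fit with free NS term recovers the generator", {
  sim <- simulate_saturation_assay(assay_sim_config(cv = 0), seed = 1)
  fit <- saturation_fit(sim$data$conc_nM, total = sim$data$total, fit_ns = TRUE)
  expect_equal(fit$kd_nM, sim$truth$kd_nM, tolerance = 1e-4)
  expect_equal(fit$bmax, sim$truth$bmax, tolerance = 1e-4)
  expect_equal(fit$ns_slope, sim$truth$ns_slope, tolerance = 1e-4)
})

test_that("internalization fractions normalize and flag undefined shares", {
  tc <- internalization_fractions(c(0, 30), c(0, 60), c(0, 40), standard = 100)
  expect_equal(tc$table$internalized_share_pct[2], 40)
  expect_equal(tc$table$total_pid[2], 100)
  expect_true(tc$table$share_undefined[1])
  expect_true(is.na(tc$table$internalized_share_pct[1]))
  expect_error(internalization_fractions(0, 1, 1, standard = 0),
               class = "normalization_error")

  # 4 degC series generated with internalization rate 0
  sim <- simulate_internalization(assay_sim_config(cv = 0), seed = 2)
  expect_equal(sim$t04$table$internalized_pid, rep(0, 5))
  shares <- sim$t04$table$internalized_share_pct
  expect_true(all(shares[!is.na(shares)] == 0))
  # and suppressed relative to 37 degC
  expect_gt(max(sim$t37$table$internalized_share_pct, na.rm = TRUE), 25)
})

test_that("percent_inhibition follows the reporting convention", {
  expect_equal(percent_inhibition(10, 0), 100)
  expect_equal(percent_inhibition(10, 10), 0)
  expect_equal(percent_inhibition(10, 0.8), 92)
  expect_error(percent_inhibition(0, 1), class = "undefined_percent_error")
})

test_that("selectivity ratios from the shipped potency panel", {
  pt <- read_potency_table()
  expect_equal(selectivity_ratio(pt, "C803-GIP", "human", "GIPR", "GLP-1R"),
               704000 / 0.7)
  expect_equal(selectivity_ratio(pt, "Ga-C803-GIP", "human", "GIPR", "GLP-1R"),
               35700 / 0.8)
  # ~1e6-fold and ~4.5e4-fold selectivity over GLP-1R
  expect_equal(selectivity_ratio(pt, "C803-GIP", "human", "GIPR", "GLP-1R") / 1e6,
               1, tolerance = 0.01)
  # identical EC50s give ratio 1
  eq <- data.frame(compound = "x", species = "s",
                   receptor = c("A", "B"), ec50_pM = c(2, 2))
  expect_equal(selectivity_ratio(eq, "x", "s", "A", "B"), 1)
  expect_error(selectivity_ratio(pt, "nope", "human", "GIPR", "GLP-1R"),
               class = "lookup_error")
})
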