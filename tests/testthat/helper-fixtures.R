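# shared fixtures, built in code at test time

ga68 <- load_reference_data("nuclide", "ga68")
icrp60 <- load_reference_data("weights", "icrp60")
phantom_m <- load_reference_data("phantom", "adult_male")
phantom_f <- load_reference_data("phantom", "adult_female")

tiny_dataset <- function(decay_corrected = TRUE) {
  samples <- data.frame(
    animal_id = c("r1", "r1", "r2", "r2"),
    organ = c("liver", "kidney", "liver", "kidney"),
    time_min = c(5, 5, 5, 5),
    activity_MBq = c(0.02, 0.05, 0.03, 0.06),
    sample_mass_g = c(10, 2, 10, 2),
    group = "baseline")
  injections <- data.frame(
    animal_id = c("r1", "r2"), injected_MBq = c(1.5, 1.5),
    body_weight_g = c(350, 350))
  biodist_dataset(samples, injections, decay_corrected = decay_corrected)
}

# dense grid search over Kd (with the exact least-squares Bmax profiled out
# at each Kd) for the one-site hyperbola: an oracle independent of the nls
# path; three zoom rounds give ~1e-4 relative resolution
grid_search_hyperbola <- function(conc, y, kd_range, n = 201) {
  lo <- log(kd_range[1]); hi <- log(kd_range[2])
  best <- c(NA, NA, Inf)
  for (round in 1:3) {
    kds <- exp(seq(lo, hi, length.out = n))
    for (kd in kds) {
      h <- conc / (kd + conc)
      b <- sum(h * y) / sum(h * h)
      ss <- sum((y - b * h)^2)
      if (ss < best[3]) best <- c(kd, b, ss)
    }
    step <- (hi - lo) / (n - 1)
    lo <- log(best[1]) - 2 * step; hi <- log(best[1]) + 2 * step
  }
  c(kd = best[1], bmax = best[2])
}
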