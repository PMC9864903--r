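# RNG hygiene: every generator seeds a local stream and restores the
# caller's RNG state on exit.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  expr
}

# mean-preserving lognormal multiplicative noise
lognoise <- function(n, cv) {
  if (cv == 0) return(rep(1, n))
  sdlog <- sqrt(log(1 + cv^2))
  exp(rnorm(n, -sdlog^2 / 2, sdlog))
}

#' Rat biodistribution kinetics configuration
#'
#' Per-organ biological (decay-corrected) fraction-of-injected models for
#' the ex vivo generator: washout organs follow
#' `f(t) = F (e^(-k_w t) - e^(-k_u t)) / norm` (normalized so the peak
#' equals `F`); excretory accumulation organs follow
#' `f(t) = F (1 - e^(-k_u t))`. Both admit closed-form time integrals with
#' physical decay, so the generator always knows its own residence times.
#'
#' The default organ set is illustrative: fast washout everywhere, a
#' monotonically accumulating kidney, a liver whose SUV stays below 1 after
#' 5 min, and peak fractions summing below 1 so complete-dissection
#' activity conservation holds.
#'
#' @param organs Data frame with columns `organ`, `peak_fraction`,
#'   `k_up_per_min`, `k_wash_per_min` (`NA` for accumulation organs),
#'   `type` (`"washout"`/`"accumulation"`), `mass_g` (rat organ mass).
#' @param cv Lognormal coefficient of variation of the measured activities.
#' @param time_min Sacrifice time points (default: the eight-point ex vivo
#'   design, 5-180 min).
#' @param n_per_time Animals per time point (default 2).
#' @param injected_MBq,body_weight_g Injection parameters.
#' @return Object of class `"biodist_kinetics"`.
#' @export
biodist_kinetics <- function(organs = NULL, cv = 0.1,
                             time_min = c(5, 10, 20, 40, 60, 90, 120, 180),
                             n_per_time = 2L, injected_MBq = 1.4,
                             body_weight_g = 350) {
  if (is.null(organs)) {
    organs <- data.frame(
      organ = c("blood", "liver", "kidney", "pancreas", "spleen", "lung",
                "heart", "muscle", "small intestine", "bone", "bone marrow",
                "brain", "thyroid", "adrenal", "testis", "stomach",
                "large intestine", "urinary bladder (rinsed)"),
      peak_fraction = c(0.30, 0.025, 0.22, 0.004, 0.003, 0.008, 0.004, 0.18,
                        0.025, 0.02, 0.01, 0.002, 0.0005, 0.0008, 0.002,
                        0.006, 0.01, 0.001),
      k_up_per_min = c(0.5, 0.5, 0.025, 0.5, 0.5, 0.5, 0.5, 0.3, 0.4, 0.3,
                       0.4, 0.5, 0.5, 0.5, 0.3, 0.4, 0.3, 0.5),
      k_wash_per_min = c(0.04, 0.012, NA, 0.03, 0.03, 0.05, 0.04, 0.035,
                         0.02, 0.01, 0.03, 0.02, 0.03, 0.03, 0.02, 0.025,
                         0.015, 0.02),
      type = c("washout", "washout", "accumulation", rep("washout", 15)),
      mass_g = c(22, 11, 2.4, 1.1, 0.8, 1.6, 1.2, 160, 9, 30, 9, 1.8, 0.02,
                 0.06, 3, 1.5, 8, 0.5),
      stringsAsFactors = FALSE)
  }
  if (cv < 0) pd_stop("config_error", "cv must be >= 0")
  w <- organs$type == "washout"
  bad <- w & !(organs$k_up_per_min > organs$k_wash_per_min)
  if (any(bad))
    pd_stop("config_error", "washout organs need k_up > k_wash >= 0: %s",
            paste(organs$organ[bad], collapse = ", "))
  if (any(organs$peak_fraction < 0) || any(organs$mass_g <= 0))
    pd_stop("config_error", "peak fractions must be >= 0 and masses > 0")
  structure(list(organs = organs, cv = cv, time_min = time_min,
                 n_per_time = as.integer(n_per_time),
                 injected_MBq = injected_MBq, body_weight_g = body_weight_g),
            class = "biodist_kinetics")
}

# biological fraction of injected activity (decay-corrected), vectorized in t
biodist_fraction <- function(row, t) {
  if (row$type == "accumulation")
    return(row$peak_fraction * (1 - exp(-row$k_up_per_min * t)))
  ku <- row$k_up_per_min; kw <- row$k_wash_per_min
  tp <- log(ku / kw) / (ku - kw)
  norm <- exp(-kw * tp) - exp(-ku * tp)
  row$peak_fraction * (exp(-kw * t) - exp(-ku * t)) / norm
}

# closed-form integral of f(t) e^(-lambda t) over [0, Inf), in hours
biodist_decayed_integral_h <- function(row, lambda_per_min) {
  lam <- lambda_per_min
  int_min <- if (row$type == "accumulation") {
    row$peak_fraction * (1 / lam - 1 / (row$k_up_per_min + lam))
  } else {
    ku <- row$k_up_per_min; kw <- row$k_wash_per_min
    tp <- log(ku / kw) / (ku - kw)
    norm <- exp(-kw * tp) - exp(-ku * tp)
    row$peak_fraction / norm * (1 / (kw + lam) - 1 / (ku + lam))
  }
  int_min / 60
}

#' Simulate an ex vivo biodistribution dataset
#'
#' Draws the two-animals-per-time-point dissection design: each animal
#' contributes every organ, with decay-corrected activities
#' `injected x f_organ(t)` under mean-preserving lognormal noise. The
#' returned truth record carries the generating fraction curves and the
#' closed-form decay-weighted integrals needed to score any downstream
#' residence-time estimate — no hidden truth.
#'
#' @param cfg A [biodist_kinetics()].
#' @param seed Integer seed; identical seeds give bit-identical datasets.
#' @return List with `dataset` (a [biodist_dataset()], decay-corrected) and
#'   `truth` (config, per-organ fraction matrix at the design times, and
#'   `decayed_integral_h` = closed-form integral of f(t) e^(-lambda t) in
#'   hours for the built-in Ga-68 decay constant).
#' @export
simulate_biodistribution <- function(cfg = biodist_kinetics(), seed = 1L) {
  nuc <- load_reference_data("nuclide", "ga68")
  lam <- decay_constant(nuc, "min")
  with_seed(seed, {
    rows <- split(cfg$organs, seq_len(nrow(cfg$organs)))
    samples <- list(); inj <- list(); aid <- 0L
    frac <- sapply(rows, function(r) biodist_fraction(r, cfg$time_min))
    frac <- matrix(frac, nrow = length(cfg$time_min),
                   dimnames = list(NULL, cfg$organs$organ))
    for (t0 in cfg$time_min) {
      ti <- match(t0, cfg$time_min)
      for (a in seq_len(cfg$n_per_time)) {
        aid <- aid + 1L
        id <- sprintf("rat%02d", aid)
        act <- cfg$injected_MBq * frac[ti, ] * lognoise(nrow(cfg$organs), cfg$cv)
        samples[[length(samples) + 1L]] <- data.frame(
          animal_id = id, organ = cfg$organs$organ, time_min = t0,
          activity_MBq = as.numeric(act), sample_mass_g = cfg$organs$mass_g,
          group = "baseline", stringsAsFactors = FALSE)
        inj[[length(inj) + 1L]] <- data.frame(
          animal_id = id, injected_MBq = cfg$injected_MBq,
          body_weight_g = cfg$body_weight_g, stringsAsFactors = FALSE)
      }
    }
    ds <- biodist_dataset(do.call(rbind, samples), do.call(rbind, inj),
                          species = "rat", decay_corrected = TRUE)
    integrals <- vapply(rows, biodist_decayed_integral_h, 0, lambda_per_min = lam)
    names(integrals) <- cfg$organs$organ
    list(dataset = ds,
         truth = list(config = cfg, fraction = frac,
                      decayed_integral_h = integrals,
                      lambda_per_min = lam))
  })
}

#' Plasma pharmacokinetics simulation configuration
#'
#' One-compartment model with first-order absorption, parameterized the way
#' the NCA reports it: dose, absorption and elimination half-lives, and
#' clearance (the apparent volume follows as CL / k_e). Defaults reproduce
#' the subcutaneous study design: sampling at 3, 6, 9.6, 19.8, 30, 60, 120
#' and 240 min with below-LOD values assigned zero.
#'
#' @param dose_mg_kg Dose, mg/kg.
#' @param t_half_abs_h,t_half_elim_h Absorption and elimination half-lives,
#'   h; must be positive and distinct.
#' @param cl_L_h_kg Plasma clearance, L/h/kg.
#' @param lod_ng_ml Limit of detection, ng/mL.
#' @param time_min Sampling times, minutes.
#' @param cv Proportional (lognormal) noise CV; 0 = noise-free.
#' @return Object of class `"pk_sim_config"`.
#' @export
pk_sim_config <- function(dose_mg_kg = 1, t_half_abs_h = 0.1,
                          t_half_elim_h = 0.38, cl_L_h_kg = 0.73,
                          lod_ng_ml = 5,
                          time_min = c(3, 6, 9.6, 19.8, 30, 60, 120, 240),
                          cv = 0) {
  if (t_half_abs_h <= 0 || t_half_elim_h <= 0)
    pd_stop("config_error", "half-lives must be positive")
  if (abs(t_half_abs_h - t_half_elim_h) < 1e-12)
    pd_stop("degenerate_model_error", "absorption and elimination half-lives must differ")
  structure(list(dose_mg_kg = dose_mg_kg, t_half_abs_h = t_half_abs_h,
                 t_half_elim_h = t_half_elim_h, cl_L_h_kg = cl_L_h_kg,
                 lod_ng_ml = lod_ng_ml, time_min = time_min, cv = cv),
            class = "pk_sim_config")
}

# closed-form concentration (ng/mL) of the absorption model at t minutes
pk_model_conc <- function(cfg, t_min) {
  ka <- log(2) / cfg$t_half_abs_h
  ke <- log(2) / cfg$t_half_elim_h
  v_L_kg <- cfg$cl_L_h_kg / ke
  c0 <- cfg$dose_mg_kg * 1e6 / (v_L_kg * 1000)  # ng/mL if fully distributed
  t_h <- t_min / 60
  c0 * ka / (ka - ke) * (exp(-ke * t_h) - exp(-ka * t_h))
}

#' Simulate a subcutaneous plasma concentration profile
#'
#' @param cfg A [pk_sim_config()].
#' @param seed Integer seed (used only when `cv > 0`).
#' @return List with `profile` (a [plasma_profile()], below-LOD samples
#'   assigned zero and flagged censored) and `truth`
#'   (`auc_h_ng_ml = dose/CL`, `t_half_h`, the model function parameters).
#' @export
simulate_plasma_pk <- function(cfg = pk_sim_config(), seed = 1L) {
  with_seed(seed, {
    conc <- pk_model_conc(cfg, cfg$time_min)
    conc <- conc * lognoise(length(conc), cfg$cv)
    cens <- conc < cfg$lod_ng_ml
    conc[cens] <- 0
    if (all(cens)) warning("all samples below the limit of detection")
    p <- plasma_profile(cfg$time_min, conc, dose_mg_kg = cfg$dose_mg_kg,
                        lod_ng_ml = cfg$lod_ng_ml, censored = cens,
                        route = "sc")
    list(profile = p,
         truth = list(auc_h_ng_ml = cfg$dose_mg_kg * 1000 / cfg$cl_L_h_kg,
                      t_half_h = cfg$t_half_elim_h,
                      cl_L_h_kg = cfg$cl_L_h_kg, config = cfg))
  })
}

#' In vitro assay simulation configuration
#'
#' Generating parameters for the saturation-binding and internalization
#' generators. Saturation defaults follow the reported assay: seven
#' concentrations 0.3-300 nM in triplicate, Kd 18.3 nM, Bmax 2.4
#' pmol/Mcells, a shallow linear non-specific component and 10%
#' proportional noise. Internalization defaults give ~60-85 %ID/Mcells
#' total binding over 2 h with roughly 40% internalized at 37 degC and
#' internalization suppressed at 4 degC.
#'
#' @param kd_nM,bmax Generating one-site parameters.
#' @param ns_slope Linear non-specific binding, (pmol/Mcells)/nM.
#' @param cv Proportional noise CV.
#' @param conc_nM Assayed concentrations.
#' @param replicates Replicates per concentration.
#' @param surface_eq Equilibrium surface binding, %ID/Mcells.
#' @param k_surface_per_min Rate of approach to surface equilibrium.
#' @param k_int_37_per_min,k_int_4_per_min Internalization rates at 37 and
#'   4 degC; the 4 degC rate must not exceed the 37 degC rate.
#' @param int_time_min Internalization sampling times.
#' @return Object of class `"assay_sim_config"`.
#' @export
assay_sim_config <- function(kd_nM = 18.3, bmax = 2.4, ns_slope = 0.002,
                             cv = 0.1,
                             conc_nM = c(0.3, 1, 3, 10, 30, 100, 300),
                             replicates = 3L,
                             surface_eq = 50, k_surface_per_min = 0.05,
                             k_int_37_per_min = 0.007, k_int_4_per_min = 0,
                             int_time_min = c(0, 30, 60, 90, 120)) {
  if (kd_nM <= 0 || bmax <= 0)
    pd_stop("config_error", "kd and bmax must be positive")
  if (cv < 0 || ns_slope < 0)
    pd_stop("config_error", "cv and ns_slope must be >= 0")
  if (k_int_37_per_min < 0 || k_int_4_per_min < 0)
    pd_stop("config_error", "internalization rates must be >= 0")
  if (k_int_4_per_min > k_int_37_per_min)
    pd_stop("config_error", "4 degC internalization rate cannot exceed the 37 degC rate")
  structure(list(kd_nM = kd_nM, bmax = bmax, ns_slope = ns_slope, cv = cv,
                 conc_nM = conc_nM, replicates = as.integer(replicates),
                 surface_eq = surface_eq, k_surface_per_min = k_surface_per_min,
                 k_int_37_per_min = k_int_37_per_min,
                 k_int_4_per_min = k_int_4_per_min,
                 int_time_min = int_time_min),
            class = "assay_sim_config")
}

#' Simulate a saturation-binding assay
#'
#' Total arm = one-site hyperbola + linear non-specific + proportional
#' noise; blocking arm = linear non-specific + noise.
#'
#' @param cfg An [assay_sim_config()].
#' @param seed Integer seed.
#' @return List with `data` (data frame `conc_nM`, `replicate`, `total`,
#'   `nonspecific`) and `truth` (generating `kd_nM`, `bmax`, `ns_slope`).
#' @export
simulate_saturation_assay <- function(cfg = assay_sim_config(), seed = 1L) {
  with_seed(seed, {
    conc <- rep(cfg$conc_nM, each = cfg$replicates)
    spec <- cfg$bmax * conc / (cfg$kd_nM + conc)
    ns <- cfg$ns_slope * conc
    total <- (spec + ns) * lognoise(length(conc), cfg$cv)
    nonspec <- ns * lognoise(length(conc), cfg$cv)
    list(data = data.frame(conc_nM = conc,
                           replicate = rep(seq_len(cfg$replicates),
                                           times = length(cfg$conc_nM)),
                           total = total, nonspecific = nonspec),
         truth = list(kd_nM = cfg$kd_nM, bmax = cfg$bmax,
                      ns_slope = cfg$ns_slope))
  })
}

# closed-form surface/internalized kinetics: surface approaches equilibrium
# S_eq at rate k_s while feeding the internal pool at rate k_int
internalization_model <- function(cfg, t, k_int) {
  s <- cfg$surface_eq * (1 - exp(-cfg$k_surface_per_min * t))
  i <- k_int * cfg$surface_eq *
    (t - (1 - exp(-cfg$k_surface_per_min * t)) / cfg$k_surface_per_min)
  list(surface = s, internalized = i)
}

#' Simulate internalization time courses at 37 and 4 degC
#'
#' @param cfg An [assay_sim_config()].
#' @param seed Integer seed.
#' @return List with `t37` and `t04` ([internalization_fractions()]
#'   objects) and `truth` (the model functions' parameters and noise-free
#'   fractions).
#' @export
simulate_internalization <- function(cfg = assay_sim_config(), seed = 1L) {
  with_seed(seed, {
    standard <- 1e6  # counts of the added-dose standard
    build <- function(k_int, temp) {
      m <- internalization_model(cfg, cfg$int_time_min, k_int)
      noisy <- function(pid) pmax(0, pid / 100 * standard *
                                    lognoise(length(pid), cfg$cv))
      internalization_fractions(cfg$int_time_min, noisy(m$surface),
                                noisy(m$internalized), standard,
                                cells_million = 1, temperature_c = temp)
    }
    t37 <- build(cfg$k_int_37_per_min, 37)
    t04 <- build(cfg$k_int_4_per_min, 4)
    m37 <- internalization_model(cfg, cfg$int_time_min, cfg$k_int_37_per_min)
    m04 <- internalization_model(cfg, cfg$int_time_min, cfg$k_int_4_per_min)
    list(t37 = t37, t04 = t04,
         truth = list(config = cfg, model_37 = m37, model_4 = m04))
  })
}

#' Simulate a cell-pellet autoradiogram with reference droplet
#'
#' Lays square pellet ROIs of given surface densities (fmol/mm2) and a
#' reference droplet of known activity on a pixel grid; expected counts are
#' density x molar activity x sensitivity x exposure x pixel area, with
#' Poisson counting noise (or none) on top of a uniform background.
#'
#' @param densities_fmol_mm2 Named vector of pellet surface densities (at
#'   most 4 pellets).
#' @param reference_bq Activity of the reference droplet, Bq.
#' @param molar_activity_bq_fmol Molar activity, Bq/fmol.
#' @param pixel_size_mm Pixel edge, mm.
#' @param sensitivity Counts per Bq per exposure unit.
#' @param exposure Exposure (arbitrary units); doubling it doubles all
#'   counts and cancels in calibration.
#' @param background_rate Expected background counts per pixel.
#' @param noise `"poisson"` or `"none"`.
#' @param seed Integer seed.
#' @return List with `image` (an [autoradiogram()] whose ROIs are the
#'   pellets, `"reference"` and `"background"`) and `truth` (generating
#'   densities and Bq/mm2).
#' @export
simulate_autoradiogram <- function(densities_fmol_mm2 = c(pellet1 = 3, pellet2 = 1),
                                   reference_bq = 100,
                                   molar_activity_bq_fmol = 60,
                                   pixel_size_mm = 0.1, sensitivity = 5,
                                   exposure = 1, background_rate = 0.5,
                                   noise = c("poisson", "none"), seed = 1L) {
  noise <- match.arg(noise)
  if (any(densities_fmol_mm2 < 0))
    pd_stop("config_error", "densities must be >= 0")
  if (length(densities_fmol_mm2) > 4L)
    pd_stop("config_error", "at most 4 pellets supported")
  with_seed(seed, {
    n <- 80L
    px_area <- pixel_size_mm^2
    expected <- matrix(background_rate, n, n)
    rois <- list()
    corners <- list(c(8, 8), c(8, 48), c(48, 8), c(48, 48))
    bq_mm2 <- densities_fmol_mm2 * molar_activity_bq_fmol
    for (i in seq_along(densities_fmol_mm2)) {
      m <- matrix(FALSE, n, n)
      r <- corners[[i]]
      m[r[1]:(r[1] + 14), r[2]:(r[2] + 14)] <- TRUE
      rois[[names(densities_fmol_mm2)[i]]] <- m
      expected[m] <- expected[m] + bq_mm2[i] * sensitivity * exposure * px_area
    }
    ref <- matrix(FALSE, n, n)
    ref[30:39, 66:75] <- TRUE
    rois[["reference"]] <- ref
    ref_area <- sum(ref) * px_area
    expected[ref] <- expected[ref] +
      (reference_bq / ref_area) * sensitivity * exposure * px_area
    bg <- matrix(FALSE, n, n)
    bg[66:75, 8:17] <- TRUE
    rois[["background"]] <- bg
    counts <- if (noise == "poisson") {
      matrix(rpois(n * n, expected), n, n)
    } else expected
    img <- autoradiogram(counts, pixel_size_mm, rois, "reference",
                         reference_bq, molar_activity_bq_fmol)
    list(image = img,
         truth = list(densities_fmol_mm2 = densities_fmol_mm2,
                      bq_per_mm2 = bq_mm2, sensitivity = sensitivity,
                      exposure = exposure, background_rate = background_rate))
  })
}
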