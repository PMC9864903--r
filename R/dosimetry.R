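#' Human organ fraction from a decay-uncorrected rat SUV curve
#'
#' Extrapolates rodent uptake to a human phantom: the fraction of injected
#' activity in a human organ is the decay-uncorrected SUV multiplied by the
#' organ-to-body mass ratio of the phantom,
#' `fraction(t) = SUV_A(t) * m_organ[g] / (1000 * body_mass[kg])`.
#' The input curve must be flagged decay-uncorrected; feeding a
#' decay-corrected curve is a state error, not a silent reinterpretation.
#'
#' @param curve A decay-uncorrected [suv_curve()].
#' @param phantom A [phantom()].
#' @param aliases Organ alias map (see [organ_aliases()]) used to resolve
#'   dissection labels to phantom organs.
#' @return Object of class `"organ_fraction_curve"`: canonical `organ`,
#'   `time_min`, `fraction` (dimensionless, between 0 and 1 for physical
#'   inputs).
#' @export
human_organ_fraction <- function(curve, phantom, aliases = organ_aliases()) {
  if (curve$decay_corrected)
    pd_stop("state_error",
            "curve '%s' is decay-corrected; residence-time extrapolation needs decay-uncorrected SUVs",
            curve$organ)
  org <- canonical_organ(curve$organ)
  if (!org %in% names(phantom$organ_masses)) {
    if (org %in% names(aliases) && aliases[[org]] %in% names(phantom$organ_masses))
      org <- aliases[[org]]
    else
      pd_stop("alias_error",
              "organ '%s' not in phantom and no alias resolves it; known aliases: %s",
              curve$organ, paste(names(aliases), collapse = ", "))
  }
  frac <- curve$mean_suv * phantom$organ_masses[[org]] /
    (1000 * phantom$body_mass_kg)
  structure(list(organ = org, time_min = curve$time_min, fraction = frac),
            class = "organ_fraction_curve")
}

#' Construct an organ fraction curve directly
#'
#' @param organ Canonical organ name.
#' @param time_min Strictly increasing times, minutes.
#' @param fraction Fraction of injected activity (decay-uncorrected).
#' @return Object of class `"organ_fraction_curve"`.
#' @export
organ_fraction_curve <- function(organ, time_min, fraction) {
  if (any(diff(time_min) <= 0))
    pd_stop("validation_error", "time_min must be strictly increasing")
  if (any(fraction < 0))
    pd_stop("validation_error", "fractions must be non-negative")
  structure(list(organ = canonical_organ(organ), time_min = time_min,
                 fraction = fraction),
            class = "organ_fraction_curve")
}

#' Residence time by trapezoid plus exponential tail
#'
#' Integrates a decay-uncorrected fraction-of-injected curve to infinity:
#' linear trapezoid over the observed span (with `f(0) = 0` prepended when
#' the first sample is after injection), plus a tail `f(t_last) / k` from a
#' single-exponential least-squares fit to the last `tail_n` points. If the
#' fitted rate is slower than physical decay (apparent accumulation, e.g. a
#' kidney retaining the tracer), the tail is clamped to the physical decay
#' constant — activity cannot outlive the nuclide — and the clamp is
#' annotated. A failed tail fit falls back to physical decay with a
#' warning annotation.
#'
#' @param curve An `"organ_fraction_curve"` (or decay-uncorrected
#'   [suv_curve()] pre-converted by [human_organ_fraction()]).
#' @param nuclide A [radionuclide()].
#' @param tail_n Number of terminal points for the tail fit (default 3).
#' @return Object of class `"residence_time"`: `tau_h` (MBq h/MBq, i.e.
#'   hours), `trapezoid_h`, `tail_h`, `tail_rate_per_h`, `clamped`,
#'   `n_tail`, `note`.
#' @export
residence_time <- function(curve, nuclide, tail_n = 3L) {
  t_h <- curve$time_min / 60
  f <- curve$fraction
  lam_h <- decay_constant(nuclide, "hour")
  if (all(f == 0))
    return(structure(list(organ = curve$organ, tau_h = 0, trapezoid_h = 0,
                          tail_h = 0, tail_rate_per_h = lam_h, clamped = FALSE,
                          n_tail = 0L, note = "all-zero curve"),
                     class = "residence_time"))
  if (t_h[1] > 0) { t_h <- c(0, t_h); f <- c(0, f) }
  trap <- trapz(t_h, f)

  # single-exponential fit to the last tail_n positive points
  note <- "tail fitted"
  clamped <- FALSE
  idx <- which(f > 0)
  idx <- tail(idx, tail_n)
  k <- NA_real_
  if (length(idx) >= 2L) {
    fit <- tryCatch(lm(log(f[idx]) ~ t_h[idx]), error = function(e) NULL)
    if (!is.null(fit)) k <- -coef(fit)[[2]]
  }
  if (!is.finite(k)) {
    k <- lam_h; clamped <- TRUE
    note <- "tail fit unavailable; physical decay used"
    warning(sprintf("organ '%s': tail fit failed; physical decay used for extrapolation",
                    curve$organ %||% "?"))
  } else if (k < lam_h) {
    k <- lam_h; clamped <- TRUE
    note <- "apparent accumulation; tail clamped to physical decay"
  }
  f_last <- f[length(f)]
  tail_int <- f_last / k
  structure(list(organ = curve$organ, tau_h = trap + tail_int,
                 trapezoid_h = trap, tail_h = tail_int, tail_rate_per_h = k,
                 clamped = clamped, n_tail = length(idx), note = note),
            class = "residence_time")
}

#' @export
print.residence_time <- function(x, ...) {
  cat(sprintf("<residence_time> %s: tau = %.4g h (trapezoid %.4g + tail %.4g; %s)\n",
              x$organ %||% "?", x$tau_h, x$trapezoid_h, x$tail_h, x$note))
  invisible(x)
}

#' Red-marrow residence time from the blood-volume model
#'
#' The marrow blood-volume model assumes the activity concentration in red
#' marrow is the blood activity concentration scaled by the red-marrow to
#' blood activity-concentration ratio (RMBLR). The marrow fraction curve is
#' therefore `blood_fraction(t) * RMBLR * m_marrow / m_blood`, which is then
#' integrated by [residence_time()]. Linearity gives
#' `tau_marrow = RMBLR * (m_marrow / m_blood) * tau_blood` for any input.
#'
#' @param blood_curve An `"organ_fraction_curve"` for blood.
#' @param phantom A [phantom()] providing `"red marrow"` and `"blood"`
#'   masses.
#' @param nuclide A [radionuclide()].
#' @param rmblr Red-marrow to blood activity-concentration ratio
#'   (default 1).
#' @param tail_n Tail points, as in [residence_time()].
#' @return A `"residence_time"` for `"red marrow"`.
#' @export
marrow_residence <- function(blood_curve, phantom, nuclide, rmblr = 1,
                             tail_n = 3L) {
  if (is.null(blood_curve))
    pd_stop("dependency_error", "marrow blood-volume model requires a blood fraction curve")
  for (org in c("red marrow", "blood"))
    if (!org %in% names(phantom$organ_masses))
      pd_stop("lookup_error", "phantom lacks a mass for '%s'", org)
  scale <- rmblr * phantom$organ_masses[["red marrow"]] /
    phantom$organ_masses[["blood"]]
  mc <- organ_fraction_curve("red marrow", blood_curve$time_min,
                             blood_curve$fraction * scale)
  residence_time(mc, nuclide, tail_n = tail_n)
}

#' Remainder-of-body residence time
#'
#' The MIRD schema needs a remainder term for activity not assigned to a
#' source organ. Two constructions are offered: `"no_excretion"`
#' (conservative default) sets remainder = T1/2 / ln 2 minus the organ
#' residence times, i.e. all unassigned activity stays in the body and
#' decays physically; `"whole_body_curve"` uses a measured whole-body
#' residence time instead of the physical bound. Both clamp at zero.
#'
#' @param organ_taus Named numeric vector of per-source residence times, h.
#' @param nuclide A [radionuclide()].
#' @param mode `"no_excretion"` or `"whole_body_curve"`.
#' @param whole_body_tau_h Whole-body residence time (required for
#'   `"whole_body_curve"`).
#' @param tol Tolerance on the physical-bound consistency check.
#' @return Remainder residence time, h.
#' @export
remainder_residence <- function(organ_taus, nuclide,
                                mode = c("no_excretion", "whole_body_curve"),
                                whole_body_tau_h = NULL, tol = 1e-6) {
  mode <- match.arg(mode)
  bound <- nuclide$half_life_min / 60 / log(2)
  total <- sum(organ_taus)
  if (total > bound * (1 + tol))
    pd_stop("inconsistency_error",
            "organ residence times sum to %.4g h, above the physical bound %.4g h",
            total, bound)
  ref <- switch(mode,
    no_excretion = bound,
    whole_body_curve = {
      if (is.null(whole_body_tau_h))
        pd_stop("validation_error", "whole_body_curve mode needs whole_body_tau_h")
      whole_body_tau_h
    })
  rem <- ref - total
  if (rem < 0) {
    warning(sprintf("remainder clamped to 0 (organ sum %.4g h exceeds reference %.4g h)",
                    total, ref))
    rem <- 0
  }
  rem
}

#' MIRD organ absorbed doses
#'
#' `D(target) = sum over sources of tau_source x S(target <- source)`, in
#' mGy/MBq (numerically equal to mSv/MBq for the photon/electron emissions
#' considered here, radiation weighting factor 1).
#'
#' @param taus Named numeric vector of residence times, h, including any
#'   `"remainder"` entry.
#' @param svalues An [svalue_table()].
#' @return Object of class `"organ_dose_table"`: data frame `organ`,
#'   `dose_mGy_per_MBq`, plus the sex attribute of the S table.
#' @export
organ_doses <- function(taus, svalues) {
  ent <- svalues$entries
  sources <- names(taus)[taus > 0]
  missing_src <- setdiff(sources, unique(ent$source))
  if (length(missing_src))
    pd_stop("table_completeness_error",
            "S-value table has no entries for source(s): %s",
            paste(missing_src, collapse = ", "))
  targets <- setdiff(unique(ent$target), "remainder")
  dose <- vapply(targets, function(tg) {
    rows <- ent[ent$target == tg & ent$source %in% names(taus), ]
    sum(rows$s_mGy_per_MBq_h * taus[rows$source])
  }, 0)
  structure(data.frame(organ = targets, dose_mGy_per_MBq = as.numeric(dose),
                       row.names = NULL),
            class = c("organ_dose_table", "data.frame"),
            sex = svalues$sex, nuclide = svalues$nuclide)
}

#' ICRP-60 effective dose from an organ equivalent-dose table
#'
#' Applies the ICRP-60 tissue weighting factors with the conventions used
#' by OLINDA 1.1: the colon dose is `0.57 x ULI wall + 0.43 x LLI wall`;
#' the esophagus takes the thymus dose as surrogate; gonads are testes
#' (male) or ovaries (female); and the remainder follows the split rule —
#' when the highest-dosed remainder organ exceeds every named tissue's
#' dose, it receives half of the remainder weight and the mass-weighted
#' mean of the other remainder organs receives the other half, otherwise
#' the full remainder weight applies to the mass-weighted mean of all
#' remainder organs.
#'
#' @param doses Named numeric vector of organ equivalent doses (mSv/MBq),
#'   canonical organ names (a `"gonads"` entry is accepted in place of the
#'   sex-specific organ), or an `"organ_dose_table"` from [organ_doses()].
#' @param weights A [tissue_weights()] (default built-in ICRP-60 set).
#' @param phantom A [phantom()] supplying sex and the remainder organ list
#'   and masses.
#' @return Object of class `"effective_dose_result"`: `effective_dose`
#'   (mSv/MBq), per-tissue `contributions` summing exactly to it, and a
#'   `remainder` report stating whether the split rule fired and for which
#'   organ.
#' @examples
#' ph <- load_reference_data("phantom", "adult_male")
#' w <- load_reference_data("weights", "icrp60")
#' d <- read_organ_dose_table(sex = "male")
#' effective_dose(d, w, ph)
#' @export
effective_dose <- function(doses, weights = load_reference_data("weights", "icrp60"),
                           phantom) {
  if (inherits(doses, "organ_dose_table"))
    doses <- setNames(doses$dose_mGy_per_MBq, doses$organ)
  names(doses) <- canonical_organ(names(doses))
  if (any(doses < 0)) pd_stop("validation_error", "doses must be non-negative")
  gonad_organ <- if (phantom$sex == "male") "testes" else "ovaries"
  get_dose <- function(org, required = TRUE) {
    if (org == "gonads") {
      if ("gonads" %in% names(doses)) return(doses[["gonads"]])
      org <- gonad_organ
    }
    if (org %in% names(doses)) return(doses[[org]])
    if (required)
      pd_stop("completeness_error", "no dose available for required tissue '%s'", org)
    NA_real_
  }

  named <- weights$weights
  tissue_dose <- vapply(names(named), function(tw) {
    switch(tw,
      "colon" = weights$colon_split[1] * get_dose("uli wall") +
                weights$colon_split[2] * get_dose("lli wall"),
      "esophagus" = get_dose(weights$esophagus_surrogate),
      get_dose(tw))
  }, 0)
  contributions <- named * tissue_dose

  # remainder: mass-weighted mean with the ICRP-60 split rule
  rem_organs <- setdiff(phantom$remainder_organs, weights$esophagus_surrogate)
  rem_organs <- rem_organs[rem_organs %in% names(doses) |
                             (rem_organs == gonad_organ & "gonads" %in% names(doses))]
  if (!length(rem_organs))
    pd_stop("completeness_error", "no remainder organ doses available")
  rem_doses <- vapply(rem_organs, get_dose, 0)
  rem_masses <- phantom$organ_masses[rem_organs]
  mwm <- function(org_set) {
    if (!length(org_set)) return(0)
    sum(rem_doses[org_set] * rem_masses[org_set]) / sum(rem_masses[org_set])
  }
  hot <- rem_organs[which.max(rem_doses)]
  split_rule <- max(rem_doses) > max(tissue_dose)
  rem_contribution <- if (split_rule) {
    0.5 * weights$remainder_weight * rem_doses[[hot]] +
      0.5 * weights$remainder_weight * mwm(setdiff(rem_organs, hot))
  } else {
    weights$remainder_weight * mwm(rem_organs)
  }
  contributions <- c(contributions, remainder = unname(rem_contribution))
  structure(list(effective_dose = sum(contributions),
                 contributions = contributions,
                 remainder = list(split_rule = split_rule,
                                  hottest_organ = hot,
                                  organs = rem_organs,
                                  weight = weights$remainder_weight),
                 sex = phantom$sex),
            class = "effective_dose_result")
}

#' @export
print.effective_dose_result <- function(x, ...) {
  cat(sprintf("ICRP-60 effective dose (%s): %.4g mSv/MBq\n", x$sex, x$effective_dose))
  cat(sprintf("  remainder rule: %s (hottest organ: %s)\n",
              if (x$remainder$split_rule) "split (half weight to hottest organ)"
              else "mass-weighted mean", x$remainder$hottest_organ))
  cb <- sort(x$contributions, decreasing = TRUE)
  for (nm in names(cb)[seq_len(min(5, length(cb)))])
    cat(sprintf("  %-22s %.4g mSv/MBq\n", nm, cb[[nm]]))
  invisible(x)
}

#' Read an organ equivalent-dose table
#'
#' @param path CSV with columns `organ`, `male_mSv_per_MBq`,
#'   `female_mSv_per_MBq` (or a single `dose_mSv_per_MBq` column); defaults
#'   to the shipped human predicted equivalent-dose table for the
#'   Ga-68-labelled GIPR tracer, extrapolated from rat biodistribution.
#' @param sex Which column to return for two-column tables.
#' @return Named numeric vector of doses, mSv/MBq.
#' @export
read_organ_dose_table <- function(path = NULL, sex = c("male", "female")) {
  sex <- match.arg(sex)
  path <- path %||% ref_file("c803gip_organ_equivalent_doses.csv")
  df <- read.csv(path, stringsAsFactors = FALSE)
  col <- if ("dose_mSv_per_MBq" %in% names(df)) "dose_mSv_per_MBq"
         else paste0(sex, "_mSv_per_MBq")
  if (!col %in% names(df))
    pd_stop("schema_error", "dose table lacks column '%s'", col)
  setNames(df[[col]], canonical_organ(df$organ))
}

#' End-to-end rat-to-human dosimetry report
#'
#' Runs the full chain on an ex vivo dataset: decay-uncorrected SUV curves,
#' human organ fractions (per sex), residence times with exponential tails,
#' the marrow blood-volume model, the remainder term, MIRD organ doses, and
#' the ICRP-60 effective dose. All intermediates are kept on the returned
#' object for audit. The computation is deterministic: rebuilding the
#' report from the same dataset is bit-identical.
#'
#' @param ds A [biodist_dataset()].
#' @param nuclide A [radionuclide()] (default built-in Ga-68).
#' @param phantoms Named list `list(male = , female = )` of [phantom()]s.
#' @param svalues Named list of [svalue_table()]s per sex; defaults to the
#'   demonstration self-dose tables (see [selfdose_svalues()] — not for
#'   clinical use).
#' @param weights A [tissue_weights()].
#' @param rmblr Marrow blood-volume model ratio (see [marrow_residence()]).
#' @param tail_n Tail points for [residence_time()].
#' @param remainder_mode See [remainder_residence()].
#' @param aliases Organ alias map.
#' @return Object of class `"dosimetry_report"`: per-sex list with
#'   `fractions`, `residence` (list of `"residence_time"`), `taus` (named
#'   vector incl. remainder), `doses`, `effective`; plus `suv_curves` and
#'   `unmapped_organs`.
#' @export
dosimetry_report <- function(ds,
                             nuclide = load_reference_data("nuclide", "ga68"),
                             phantoms = list(
                               male = load_reference_data("phantom", "adult_male"),
                               female = load_reference_data("phantom", "adult_female")),
                             svalues = NULL,
                             weights = load_reference_data("weights", "icrp60"),
                             rmblr = 1, tail_n = 3L,
                             remainder_mode = "no_excretion",
                             aliases = organ_aliases()) {
  curves <- build_suv_curves(ds, nuclide, decay_corrected = FALSE)
  per_sex <- list()
  unmapped <- character()
  for (sex in names(phantoms)) {
    ph <- phantoms[[sex]]
    sv <- if (is.null(svalues)) selfdose_svalues(ph, nuclide) else svalues[[sex]]
    fractions <- list()
    for (org in names(curves)) {
      fc <- tryCatch(human_organ_fraction(curves[[org]], ph, aliases),
                     petdosim_error = function(e) NULL)
      if (is.null(fc)) { unmapped <- union(unmapped, org); next }
      fractions[[fc$organ]] <- fc
    }
    if (!length(fractions))
      pd_stop("validation_error", "no organ maps onto the %s phantom", sex)
    res <- lapply(fractions, residence_time, nuclide = nuclide, tail_n = tail_n)
    # blood feeds the marrow model and is not itself a dose source
    if ("blood" %in% names(fractions)) {
      res[["red marrow"]] <- marrow_residence(fractions[["blood"]], ph, nuclide,
                                              rmblr = rmblr, tail_n = tail_n)
      res[["blood"]] <- NULL
    }
    taus <- vapply(res, `[[`, 0, "tau_h")
    taus["remainder"] <- remainder_residence(taus, nuclide, mode = remainder_mode)
    doses <- organ_doses(taus, sv)
    dose_vec <- setNames(doses$dose_mGy_per_MBq, doses$organ)
    # effective dose needs every named tissue; absent targets count as zero
    # dose under the self-dose demonstration table
    all_named <- unique(c(names(ph$organ_masses), "gonads"))
    dose_full <- setNames(rep(0, length(all_named)), all_named)
    dose_full[names(dose_vec)] <- dose_vec
    eff <- effective_dose(dose_full, weights, ph)
    per_sex[[sex]] <- list(fractions = fractions, residence = res, taus = taus,
                           doses = doses, effective = eff)
  }
  structure(list(per_sex = per_sex, suv_curves = curves,
                 unmapped_organs = unmapped,
                 settings = list(rmblr = rmblr, tail_n = tail_n,
                                 remainder_mode = remainder_mode,
                                 nuclide = nuclide$name,
                                 svalue_note = if (is.null(svalues))
                                   "demonstration self-dose table" else "user-supplied")),
            class = "dosimetry_report")
}

#' @export
print.dosimetry_report <- function(x, ...) {
  cat("Rat-to-human dosimetry report\n")
  cat(sprintf("  nuclide: %s; S-values: %s; remainder: %s\n",
              x$settings$nuclide, x$settings$svalue_note, x$settings$remainder_mode))
  if (length(x$unmapped_organs))
    cat(sprintf("  unmapped organs (excluded): %s\n",
                paste(x$unmapped_organs, collapse = ", ")))
  for (sex in names(x$per_sex)) {
    ps <- x$per_sex[[sex]]
    cat(sprintf("  %s: sum tau = %.3g h (remainder %.3g h); effective dose = %.4g mSv/MBq\n",
                sex, sum(ps$taus), ps$taus[["remainder"]],
                ps$effective$effective_dose))
  }
  invisible(x)
}
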