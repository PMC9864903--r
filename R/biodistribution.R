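#' Standardized uptake value
#'
#' SUV = (tissue activity / tissue mass) / (injected activity / body
#' weight). The ratio is dimensionless and invariant under a common
#' rescaling of the two activities (units cancel); activities must simply
#' share a unit, as must the two masses.
#'
#' @param activity Tissue activity (e.g. MBq), same unit as `injected`.
#' @param sample_mass_g Tissue sample mass in g.
#' @param injected Injected activity.
#' @param body_weight_g Body weight in g.
#' @return Numeric vector of SUVs.
#' @examples
#' compute_suv(0.003, 0.5, 1.5, 350)  # 1.4
#' @export
compute_suv <- function(activity, sample_mass_g, injected, body_weight_g) {
  if (any(!(sample_mass_g > 0)) || any(!(injected > 0)) || any(!(body_weight_g > 0)))
    pd_stop("validation_error", "masses and injected activity must be positive")
  (activity / sample_mass_g) / (injected / body_weight_g)
}

#' Per-organ SUV time course
#'
#' @param organ Organ label.
#' @param time_min Strictly increasing times post injection, minutes.
#' @param mean_suv,sd_suv Mean and SD of the SUV over animals at each time.
#' @param n Animals per time point.
#' @param decay_corrected Decay-correction state of the underlying
#'   activities; carried explicitly so downstream stages can check it.
#' @return An object of class `"suv_curve"`.
#' @export
suv_curve <- function(organ, time_min, mean_suv, sd_suv = 0, n = 1L,
                      decay_corrected = TRUE) {
  if (length(time_min) && any(diff(time_min) <= 0))
    pd_stop("validation_error", "time_min must be strictly increasing")
  sd_suv <- rep_len(sd_suv, length(time_min))
  n <- rep_len(as.integer(n), length(time_min))
  if (any(n < 1L)) pd_stop("validation_error", "n must be >= 1 at every time")
  if (any(sd_suv < 0)) pd_stop("validation_error", "sd_suv must be >= 0")
  structure(list(organ = organ, time_min = time_min, mean_suv = mean_suv,
                 sd_suv = sd_suv, n = n, decay_corrected = decay_corrected),
            class = "suv_curve")
}

#' @export
print.suv_curve <- function(x, ...) {
  cat(sprintf("<suv_curve> %s (%s), %d time points\n", x$organ,
              if (x$decay_corrected) "decay-corrected" else "decay-uncorrected",
              length(x$time_min)))
  print(as.data.frame(x), row.names = FALSE)
  invisible(x)
}

#' @export
as.data.frame.suv_curve <- function(x, ...) {
  data.frame(organ = x$organ, time_min = x$time_min, mean_suv = x$mean_suv,
             sd_suv = x$sd_suv, n = x$n)
}

#' @export
plot.suv_curve <- function(x, ...) {
  up <- x$mean_suv + x$sd_suv
  lo <- pmax(0, x$mean_suv - x$sd_suv)
  plot(x$time_min, x$mean_suv, type = "b", pch = 16,
       xlab = "time post injection (min)", ylab = "SUV",
       ylim = range(0, up), main = x$organ, ...)
  has_sd <- x$sd_suv > 0
  if (any(has_sd))
    arrows(x$time_min[has_sd], lo[has_sd], x$time_min[has_sd], up[has_sd],
           angle = 90, code = 3, length = 0.03)
  invisible(x)
}

#' Build per-organ SUV curves from a dataset
#'
#' Converts each sample to an SUV, adjusts the decay-correction state to the
#' requested one (using `nuclide` and the sample time), and aggregates mean,
#' SD and animal count per (organ, time).
#'
#' @param ds A [biodist_dataset()].
#' @param nuclide A [radionuclide()]; required when the dataset's
#'   decay-correction state differs from `decay_corrected`.
#' @param decay_corrected State requested for the output curves. `FALSE`
#'   yields the decay-uncorrected SUVs used for residence-time integration.
#' @param group Which study arm to aggregate (default `"baseline"`).
#' @return Named list of [suv_curve()] objects, one per organ.
#' @export
build_suv_curves <- function(ds, nuclide = NULL, decay_corrected = TRUE,
                             group = "baseline") {
  s <- ds$samples[ds$samples$group == group, , drop = FALSE]
  if (!nrow(s)) pd_stop("validation_error", "no samples in group '%s'", group)
  inj <- ds$injections[match(s$animal_id, ds$injections$animal_id), ]
  act <- s$activity_MBq
  if (ds$decay_corrected != decay_corrected) {
    if (is.null(nuclide))
      pd_stop("state_error",
              "dataset is %s but %s curves requested; supply a nuclide",
              if (ds$decay_corrected) "decay-corrected" else "decay-uncorrected",
              if (decay_corrected) "decay-corrected" else "decay-uncorrected")
    dir <- if (decay_corrected) "correct" else "uncorrect"
    act <- decay_transform(act, s$time_min, nuclide, dir)
  }
  suv <- compute_suv(act, s$sample_mass_g, inj$injected_MBq, inj$body_weight_g)
  out <- list()
  for (org in unique(s$organ)) {
    i <- s$organ == org
    tt <- sort(unique(s$time_min[i]))
    agg <- vapply(tt, function(t0) {
      v <- suv[i & s$time_min == t0]
      c(mean(v), if (length(v) > 1L) sd(v) else 0, length(v))
    }, numeric(3))
    out[[org]] <- suv_curve(org, tt, agg[1, ], agg[2, ], as.integer(agg[3, ]),
                            decay_corrected = decay_corrected)
  }
  out
}

#' Ratio of two organ SUV curves
#'
#' Elementwise `mean(a) / mean(b)` on an identical time grid; no implicit
#' interpolation. Times where the denominator is zero are returned as `NA`
#' and flagged in the `undefined` column rather than reported as infinite.
#'
#' @param curve_a,curve_b [suv_curve()] objects on identical time grids.
#' @return Data frame with `time_min`, `ratio`, `undefined`.
#' @export
tissue_ratio <- function(curve_a, curve_b) {
  if (length(curve_a$time_min) != length(curve_b$time_min) ||
      any(curve_a$time_min != curve_b$time_min))
    pd_stop("alignment_error", "time grids differ between '%s' and '%s'",
            curve_a$organ, curve_b$organ)
  undef <- curve_b$mean_suv == 0
  r <- ifelse(undef, NA_real_, curve_a$mean_suv / curve_b$mean_suv)
  data.frame(time_min = curve_a$time_min, ratio = r, undefined = undef)
}

#' Blocking (displacement) effect between study arms
#'
#' Percent block = 100 x (1 - mean(blocked) / mean(baseline)), with the
#' group difference tested by one-way ANOVA (for two groups this is
#' equivalent to the two-sample t-test, F = t^2). No multiple-testing
#' correction is applied across organs; the result carries this as
#' metadata.
#'
#' @param baseline,blocked Numeric vectors of per-animal SUVs (or uptake
#'   values) for the two arms.
#' @param organ Optional organ label for reporting.
#' @return An object of class `"blocking_result"`: means, `percent_block`,
#'   `f_statistic`, `p_value`, group sizes.
#' @export
blocking_effect <- function(baseline, blocked, organ = NA_character_) {
  if (!length(baseline) || !length(blocked))
    pd_stop("validation_error", "both groups must be non-empty")
  mb0 <- mean(baseline); mb1 <- mean(blocked)
  if (mb0 == 0)
    pd_stop("undefined_percent_error", "baseline mean is zero; percent block undefined")
  pct <- 100 * (1 - mb1 / mb0)
  y <- c(baseline, blocked)
  g <- factor(rep(c("baseline", "blocked"), c(length(baseline), length(blocked))))
  f_stat <- p <- NA_real_
  if (length(y) > 2L) {
    tab <- suppressWarnings(anova(aov(y ~ g)))  # degenerate fits handled below
    f_stat <- tab[["F value"]][1]
    p <- tab[["Pr(>F)"]][1]
    if (is.nan(f_stat) && tab[["Sum Sq"]][1] < 1e-300) { # zero between & within
      f_stat <- 0; p <- 1
    }
  }
  structure(list(organ = organ, mean_baseline = mb0, mean_blocked = mb1,
                 percent_block = pct, f_statistic = f_stat, p_value = p,
                 n_baseline = length(baseline), n_blocked = length(blocked),
                 multiplicity_correction = "none"),
            class = "blocking_result")
}

#' @export
print.blocking_result <- function(x, ...) {
  cat(sprintf("<blocking_result>%s baseline %.3g vs blocked %.3g: %.1f%% block (F = %.3g, p = %.3g)\n",
              if (is.na(x$organ)) "" else paste0(" ", x$organ),
              x$mean_baseline, x$mean_blocked, x$percent_block,
              x$f_statistic, x$p_value))
  invisible(x)
}
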