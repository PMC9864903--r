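#' Plasma concentration-time profile
#'
#' @param time_min Strictly increasing sampling times, minutes post dose.
#' @param conc_ng_ml Plasma concentrations, ng/mL; non-negative. Values
#'   below the limit of detection are conventionally recorded as 0 and
#'   flagged censored.
#' @param dose_mg_kg Administered dose, mg/kg.
#' @param lod_ng_ml Optional limit of detection; concentrations strictly
#'   below it are flagged censored (unless `censored` is given explicitly).
#' @param censored Optional logical vector overriding the LOD rule.
#' @param route Administration route; `"sc"` (extravascular, C(0) = 0) or
#'   `"iv"`.
#' @return An object of class `"plasma_profile"`.
#' @export
plasma_profile <- function(time_min, conc_ng_ml, dose_mg_kg,
                           lod_ng_ml = NA_real_, censored = NULL,
                           route = c("sc", "iv")) {
  route <- match.arg(route)
  if (any(diff(time_min) <= 0))
    pd_stop("validation_error", "time_min must be strictly increasing")
  if (any(conc_ng_ml < 0))
    pd_stop("validation_error", "concentrations must be non-negative")
  if (!is_number(dose_mg_kg) || dose_mg_kg <= 0)
    pd_stop("validation_error", "dose_mg_kg must be positive")
  if (is.null(censored))
    censored <- if (is.na(lod_ng_ml)) rep(FALSE, length(time_min))
                else conc_ng_ml < lod_ng_ml
  structure(list(time_min = time_min, conc_ng_ml = conc_ng_ml,
                 dose_mg_kg = dose_mg_kg, lod_ng_ml = lod_ng_ml,
                 censored = censored, route = route),
            class = "plasma_profile")
}

#' @export
print.plasma_profile <- function(x, ...) {
  cat(sprintf("<plasma_profile> %s, %.3g mg/kg, %d samples (%d censored)\n",
              x$route, x$dose_mg_kg, length(x$time_min), sum(x$censored)))
  invisible(x)
}

#' Terminal half-life by log-linear regression
#'
#' Least-squares regression of log concentration on time over the terminal
#' window. Censored and zero concentrations are excluded; the slope must be
#' negative.
#'
#' @param p A [plasma_profile()].
#' @param window Optional numeric `c(t_from, t_to)` in minutes restricting
#'   the points used (inclusive).
#' @param n_points When `window` is `NULL`, use the last `n_points` positive
#'   uncensored samples (default 3).
#' @return Object of class `"terminal_fit"`: `t_half_h`, `k_per_h`,
#'   `r_squared`, `n_points`, `time_min` used.
#' @export
terminal_half_life <- function(p, window = NULL, n_points = 3L) {
  usable <- !p$censored & p$conc_ng_ml > 0
  if (!is.null(window))
    usable <- usable & p$time_min >= window[1] & p$time_min <= window[2]
  else if (sum(usable) > n_points)
    usable[usable] <- seq_len(sum(usable)) > sum(usable) - n_points
  if (sum(usable) < 2L)
    pd_stop("insufficiency_error",
            "need >= 2 positive uncensored points in the terminal window, have %d",
            sum(usable))
  t <- p$time_min[usable]; y <- log(p$conc_ng_ml[usable])
  fit <- lm(y ~ t)
  slope <- coef(fit)[["t"]]
  if (slope >= -1e-12)  # zero within numerical noise: no decline
    pd_stop("no_terminal_decline_error",
            "no terminal decline: regression slope is %.3g / min", slope)
  r2 <- if (length(t) > 2L) suppressWarnings(summary(fit)$r.squared) else 1
  structure(list(t_half_h = log(2) / (-slope) / 60,
                 k_per_h = -slope * 60, r_squared = r2,
                 n_points = length(t), time_min = t),
            class = "terminal_fit")
}

#' @export
print.terminal_fit <- function(x, ...) {
  cat(sprintf("<terminal_fit> t1/2 = %.4g h (k = %.4g / h, R2 = %.4f, %d points)\n",
              x$t_half_h, x$k_per_h, x$r_squared, x$n_points))
  invisible(x)
}

#' Area under the plasma curve to infinity
#'
#' Linear trapezoid over the observed span plus a `C_last / k` exponential
#' tail from the terminal slope. For extravascular dosing a (0, 0) anchor is
#' prepended; for intravenous profiles C(0) is back-extrapolated from the
#' first two positive samples.
#'
#' Censored points assigned zero follow the profile's own convention when
#' `censored_zero = "observed"`: the zeros enter the trapezoid as observed
#' values and, when the last sample is such a zero, no exponential tail is
#' added. `censored_zero = "exclude"` drops censored points and
#' extrapolates from the last positive sample instead.
#'
#' @param p A [plasma_profile()].
#' @param censored_zero `"observed"` (default) or `"exclude"`.
#' @param tail Add the exponential tail (default `TRUE`).
#' @param n_points Terminal points for the tail slope (see
#'   [terminal_half_life()]).
#' @return Object of class `"auc_result"`: `auc_h_ng_ml`, `auc_observed`,
#'   `auc_tail`, `extrapolated_fraction`, `k_per_h`, `zero_profile` flag.
#' @export
auc_inf <- function(p, censored_zero = c("observed", "exclude"),
                    tail = TRUE, n_points = 3L) {
  censored_zero <- match.arg(censored_zero)
  keep <- rep(TRUE, length(p$time_min))
  if (censored_zero == "exclude") keep <- !p$censored
  t <- p$time_min[keep]; y <- p$conc_ng_ml[keep]
  y[p$censored[keep]] <- 0
  if (all(y == 0)) {
    warning("all-zero profile; AUC = 0")
    return(structure(list(auc_h_ng_ml = 0, auc_observed = 0, auc_tail = 0,
                          extrapolated_fraction = 0, k_per_h = NA_real_,
                          zero_profile = TRUE), class = "auc_result"))
  }
  if (t[1] > 0) {
    c0 <- if (p$route == "sc") 0 else {
      # IV: log-linear back-extrapolation of the first two positive points
      i <- which(y > 0)[1:2]
      if (any(is.na(i))) y[which(y > 0)[1]]
      else exp(log(y[i[1]]) - t[i[1]] * diff(log(y[i]))/diff(t[i]))
    }
    t <- c(0, t); y <- c(c0, y)
  }
  auc_obs <- trapz(t, y) / 60  # min*ng/mL -> h*ng/mL
  auc_tail <- 0; k <- NA_real_
  last_zero <- y[length(y)] == 0
  if (tail && !last_zero) {
    tf <- terminal_half_life(p, n_points = n_points)
    k <- tf$k_per_h
    auc_tail <- y[length(y)] / k
  }
  total <- auc_obs + auc_tail
  structure(list(auc_h_ng_ml = total, auc_observed = auc_obs,
                 auc_tail = auc_tail,
                 extrapolated_fraction = if (total > 0) auc_tail / total else 0,
                 k_per_h = k, zero_profile = FALSE),
            class = "auc_result")
}

#' @export
print.auc_result <- function(x, ...) {
  cat(sprintf("<auc_result> AUC_inf = %.4g h*ng/mL (%.1f%% extrapolated)\n",
              x$auc_h_ng_ml, 100 * x$extrapolated_fraction))
  invisible(x)
}

#' Plasma clearance from dose and AUC
#'
#' CL = dose / AUC_inf with unit conversion:
#' mg/kg divided by h*ng/mL gives L/h/kg after multiplying by 1000.
#'
#' @param dose_mg_kg Dose, mg/kg.
#' @param auc_h_ng_ml AUC to infinity, h*ng/mL (or an [auc_inf()] result).
#' @return Clearance in L/h/kg.
#' @examples
#' clearance(1, 1370)  # ~0.73 L/h/kg
#' @export
clearance <- function(dose_mg_kg, auc_h_ng_ml) {
  if (inherits(auc_h_ng_ml, "auc_result")) auc_h_ng_ml <- auc_h_ng_ml$auc_h_ng_ml
  if (!is_number(dose_mg_kg) || dose_mg_kg <= 0)
    pd_stop("validation_error", "dose must be positive")
  if (!is_number(auc_h_ng_ml) || auc_h_ng_ml <= 0)
    pd_stop("division_guard_error", "AUC must be positive to compute clearance")
  dose_mg_kg * 1000 / auc_h_ng_ml
}

#' Non-compartmental analysis of a plasma profile
#'
#' Convenience wrapper running [terminal_half_life()], [auc_inf()] and
#' [clearance()] and returning one classed result.
#'
#' @inheritParams auc_inf
#' @inheritParams terminal_half_life
#' @return Object of class `"pk_nca"` with `t_half_h`, `auc_h_ng_ml`,
#'   `cl_L_h_kg`, `extrapolated_fraction`, `terminal_points_used` and the
#'   underlying fit objects.
#' @export
pk_nca <- function(p, window = NULL, n_points = 3L,
                   censored_zero = c("observed", "exclude")) {
  censored_zero <- match.arg(censored_zero)
  tf <- terminal_half_life(p, window = window, n_points = n_points)
  auc <- auc_inf(p, censored_zero = censored_zero, n_points = n_points)
  structure(list(t_half_h = tf$t_half_h, auc_h_ng_ml = auc$auc_h_ng_ml,
                 cl_L_h_kg = clearance(p$dose_mg_kg, auc),
                 extrapolated_fraction = auc$extrapolated_fraction,
                 terminal_points_used = tf$n_points,
                 terminal_fit = tf, auc = auc, profile = p),
            class = "pk_nca")
}

#' @export
print.pk_nca <- function(x, ...) {
  cat("Non-compartmental analysis\n")
  cat(sprintf("  terminal t1/2 : %.3g h (%d points, R2 = %.4f)\n",
              x$t_half_h, x$terminal_points_used, x$terminal_fit$r_squared))
  cat(sprintf("  AUC_inf       : %.4g h*ng/mL (%.1f%% extrapolated)\n",
              x$auc_h_ng_ml, 100 * x$extrapolated_fraction))
  cat(sprintf("  clearance     : %.3g L/h/kg\n", x$cl_L_h_kg))
  invisible(x)
}
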