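#' Radionuclide physical constants
#'
#' Container for the physical data the pipeline needs about a positron
#' emitter: half-life (minutes), the mean non-penetrating (electron/positron)
#' energy emitted per decay, and the positron branching fraction. The
#' built-in Ga-68 entry is loaded with
#' `load_reference_data("nuclide", "ga68")`.
#'
#' @param name Nuclide label, e.g. `"Ga-68"`.
#' @param half_life_min Physical half-life in minutes; must be positive.
#' @param np_energy_mev Mean non-penetrating energy per decay in MeV
#'   (optional; used only by the demonstration self-dose S-value builder).
#' @param branching Decay branching fraction in (0, 1] (optional).
#' @return An object of class `"radionuclide"`.
#' @examples
#' ga68 <- radionuclide("Ga-68", half_life_min = 67.71)
#' decay_transform(1, t_min = 67.71, ga68, "uncorrect")  # 0.5
#' @export
radionuclide <- function(name, half_life_min, np_energy_mev = NA_real_,
                         branching = NA_real_) {
  if (!is_number(half_life_min) || half_life_min <= 0)
    pd_stop("validation_error", "half_life_min must be a positive number")
  if (!is.na(branching) && (branching <= 0 || branching > 1))
    pd_stop("validation_error", "branching must lie in (0, 1]")
  structure(
    list(name = as.character(name), half_life_min = half_life_min,
         np_energy_mev = np_energy_mev, branching = branching),
    class = "radionuclide"
  )
}

#' @export
print.radionuclide <- function(x, ...) {
  cat(sprintf("<radionuclide> %s  T1/2 = %.4g min (%.4g h)\n",
              x$name, x$half_life_min, x$half_life_min / 60))
  if (!is.na(x$np_energy_mev))
    cat(sprintf("  non-penetrating energy: %.4g MeV/decay\n", x$np_energy_mev))
  invisible(x)
}

#' Decay constant of a radionuclide
#'
#' @param nuclide A [radionuclide()].
#' @param per Time unit of the returned rate, `"min"` or `"hour"`.
#' @return lambda = ln(2) / half-life, in the requested unit.
#' @export
decay_constant <- function(nuclide, per = c("min", "hour")) {
  per <- match.arg(per)
  lam <- log(2) / nuclide$half_life_min
  if (per == "hour") lam * 60 else lam
}

#' Decay-correct or decay-uncorrect a measured value
#'
#' Multiplies an activity (or any activity-proportional quantity such as an
#' SUV) by `exp(+lambda * t)` to refer it back to the time of injection
#' (`direction = "correct"`), or by `exp(-lambda * t)` to restore the
#' as-measured, physically decaying value (`direction = "uncorrect"`).
#' The two directions are exact inverses.
#'
#' @param value Numeric vector of activities or SUVs.
#' @param t_min Time(s) post injection in minutes; non-negative, recycled
#'   against `value`.
#' @param nuclide A [radionuclide()].
#' @param direction `"correct"` or `"uncorrect"`.
#' @return Transformed numeric vector, same semantics as `value`.
#' @export
decay_transform <- function(value, t_min, nuclide,
                            direction = c("correct", "uncorrect")) {
  direction <- match.arg(direction)
  if (any(t_min < 0)) pd_stop("domain_error", "t_min must be non-negative")
  lam <- decay_constant(nuclide, "min")
  sgn <- if (direction == "correct") 1 else -1
  value * exp(sgn * lam * t_min)
}
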