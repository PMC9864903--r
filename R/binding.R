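#' Specific binding by blocking-arm subtraction
#'
#' Specific = total - non-specific, elementwise on matched concentration
#' grids. Negative differences (possible with noisy data) are clamped to 0;
#' the number of clamped points is returned in the `"n_clamped"` attribute
#' and reported with a warning.
#'
#' @param total,nonspecific Numeric vectors of bound ligand on the same
#'   concentration grid (pmol per million cells).
#' @return Numeric vector of specific binding with attribute `n_clamped`.
#' @export
specific_binding <- function(total, nonspecific) {
  if (length(total) != length(nonspecific))
    pd_stop("alignment_error",
            "total (%d) and nonspecific (%d) grids differ in length",
            length(total), length(nonspecific))
  s <- total - nonspecific
  n_clamped <- sum(s < 0)
  if (n_clamped) {
    warning(sprintf("%d negative specific-binding value(s) clamped to 0", n_clamped))
    s[s < 0] <- 0
  }
  structure(s, n_clamped = n_clamped)
}

#' One-site saturation binding fit
#'
#' Fits the one-site hyperbola `B(C) = Bmax * C / (Kd + C)` to specific
#' binding by nonlinear least squares. With a measured non-specific arm
#' (the usual design: binding in the presence of excess unlabelled ligand),
#' specific binding is formed by subtraction first. Without a blocking arm,
#' set `fit_ns = TRUE` to fit total binding with an additional free linear
#' non-specific term `ns * C`.
#'
#' Starting values are taken from the data: `Bmax0` is the largest mean
#' specific binding, `Kd0` the concentration at half of `Bmax0` by linear
#' interpolation.
#'
#' @param conc_nM Ligand concentrations, nM (replicates repeat the value).
#' @param total Total bound, pmol per million cells.
#' @param nonspecific Non-specific bound on the same grid (optional).
#' @param specific Pre-computed specific binding (alternative to
#'   `total`/`nonspecific`).
#' @param fit_ns Fit a free linear non-specific slope on total binding.
#' @return Object of class `"saturation_fit"` with `kd_nM`, `bmax`, their
#'   standard errors, the underlying `nls` fit, and the data used.
#' @examples
#' conc <- c(0.3, 1, 3, 10, 30, 100, 300)
#' b <- 2.4 * conc / (18.3 + conc)
#' fit <- saturation_fit(conc, specific = b)
#' coef(fit)  # kd ~ 18.3, bmax ~ 2.4
#' @export
saturation_fit <- function(conc_nM, total = NULL, nonspecific = NULL,
                           specific = NULL, fit_ns = FALSE) {
  if (length(unique(conc_nM)) < 4L)
    pd_stop("validation_error", "need >= 4 distinct concentrations")
  if (any(conc_nM <= 0))
    pd_stop("validation_error", "concentrations must be positive")
  if (is.null(specific) && !fit_ns) {
    if (is.null(total) || is.null(nonspecific))
      pd_stop("validation_error",
              "supply specific, or total + nonspecific, or total with fit_ns = TRUE")
    specific <- suppressWarnings(specific_binding(total, nonspecific))
  }
  y <- if (fit_ns) total else as.numeric(specific)
  if (is.null(y)) pd_stop("validation_error", "no binding values supplied")

  # data-driven start: Bmax0 = max mean bound; Kd0 = conc at half Bmax0
  mb <- vapply(split(y, conc_nM), mean, 0)
  cu <- as.numeric(names(mb))
  o <- order(cu); cu <- cu[o]; mb <- mb[o]
  bmax0 <- max(mb)
  kd0 <- tryCatch(approx(mb, cu, xout = bmax0 / 2, ties = "ordered")$y,
                  error = function(e) NA_real_)
  if (!is.finite(kd0) || kd0 <= 0) kd0 <- median(cu)

  df <- data.frame(conc = conc_nM, y = y)
  fit <- tryCatch(
    if (fit_ns)
      minpack.lm::nlsLM(y ~ bmax * conc / (kd + conc) + ns * conc, data = df,
                        start = list(bmax = bmax0, kd = kd0, ns = 0),
                        lower = c(0, 1e-9, 0),
                        control = minpack.lm::nls.lm.control(maxiter = 200))
    else
      minpack.lm::nlsLM(y ~ bmax * conc / (kd + conc), data = df,
                        start = list(bmax = bmax0, kd = kd0),
                        lower = c(0, 1e-9),
                        control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e)
      pd_stop("fit_error", "saturation fit failed to converge: %s (start bmax = %.3g, kd = %.3g)",
              conditionMessage(e), bmax0, kd0))
  est <- coef(fit)
  se <- tryCatch(sqrt(diag(vcov(fit))), error = function(e) rep(NA_real_, length(est)))
  names(se) <- names(est)
  if (est[["kd"]] < min(conc_nM) / 100 || est[["kd"]] > max(conc_nM) * 100)
    warning(sprintf("fitted Kd (%.3g nM) extrapolates far beyond the assayed range", est[["kd"]]))
  structure(list(kd_nM = est[["kd"]], bmax = est[["bmax"]],
                 ns_slope = if (fit_ns) est[["ns"]] else NA_real_,
                 se_kd = se[["kd"]], se_bmax = se[["bmax"]],
                 fit = fit, data = df,
                 n_clamped = attr(specific, "n_clamped") %||% 0L),
            class = "saturation_fit")
}

#' @export
coef.saturation_fit <- function(object, ...) {
  c(kd = object$kd_nM, bmax = object$bmax)
}

#' @export
print.saturation_fit <- function(x, ...) {
  cat("One-site saturation binding fit\n")
  cat(sprintf("  Kd   = %.3g +/- %.2g nM\n", x$kd_nM, x$se_kd))
  cat(sprintf("  Bmax = %.3g +/- %.2g pmol/Mcells\n", x$bmax, x$se_bmax))
  if (!is.na(x$ns_slope))
    cat(sprintf("  NS slope = %.3g (pmol/Mcells)/nM\n", x$ns_slope))
  invisible(x)
}

#' @export
summary.saturation_fit <- function(object, ...) summary(object$fit, ...)

#' @export
predict.saturation_fit <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) newdata <- object$data
  if (is.numeric(newdata)) newdata <- data.frame(conc = newdata)
  predict(object$fit, newdata = newdata)
}

#' @export
plot.saturation_fit <- function(x, ...) {
  plot(x$data$conc, x$data$y, log = "x", pch = 16,
       xlab = "ligand concentration (nM)",
       ylab = "specific bound (pmol/Mcells)", ...)
  cg <- exp(seq(log(min(x$data$conc)), log(max(x$data$conc)), length.out = 100))
  lines(cg, predict(x, cg))
  invisible(x)
}

#' Internalization time course from counting data
#'
#' Converts membrane-bound (acid-wash) and internalized (lysate) counts to
#' percent of the added dose per million cells, and reports the internalized
#' share of total cell-associated ligand. Times where the total is zero get
#' an undefined (NA) share rather than NaN.
#'
#' @param time_min Sampling times, minutes.
#' @param membrane,internalized Counts for the two fractions.
#' @param standard Counts of the added-dose standard (whole incubation
#'   dose); must be positive.
#' @param cells_million Cells per dish in millions (default 1).
#' @param temperature_c Incubation temperature, degrees C (metadata).
#' @return Object of class `"internalization_tc"` wrapping a data frame
#'   with `%ID/Mcells` columns and `internalized_share_pct`.
#' @export
internalization_fractions <- function(time_min, membrane, internalized,
                                      standard, cells_million = 1,
                                      temperature_c = 37) {
  if (!(standard > 0))
    pd_stop("normalization_error", "standard counts must be positive")
  if (length(membrane) != length(time_min) ||
      length(internalized) != length(time_min))
    pd_stop("alignment_error", "fractions and times differ in length")
  if (any(membrane < 0) || any(internalized < 0))
    pd_stop("validation_error", "counts must be non-negative")
  to_pid <- function(x) 100 * x / standard / cells_million
  mem <- to_pid(membrane); int <- to_pid(internalized)
  tot <- mem + int
  share <- ifelse(tot > 0, 100 * int / tot, NA_real_)
  structure(list(table = data.frame(
    time_min = time_min, membrane_pid = mem, internalized_pid = int,
    total_pid = tot, internalized_share_pct = share,
    share_undefined = tot == 0), temperature_c = temperature_c),
    class = "internalization_tc")
}

#' @export
print.internalization_tc <- function(x, ...) {
  cat(sprintf("<internalization_tc> %.0f degC\n", x$temperature_c))
  print(x$table, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Percent inhibition of uptake by blocking
#'
#' 100 x (1 - blocked / baseline); the convention used to report
#' autoradiographic blocking percentages.
#'
#' @param baseline,blocked Uptake values (same unit); baseline must be
#'   positive.
#' @return Percent inhibition.
#' @examples
#' percent_inhibition(10, 0.8)  # 92
#' @export
percent_inhibition <- function(baseline, blocked) {
  if (!(baseline > 0))
    pd_stop("undefined_percent_error", "baseline uptake must be positive")
  100 * (1 - blocked / baseline)
}

#' Read a functional-potency (EC50) table
#'
#' @param path CSV with columns `compound`, `species`, `receptor`,
#'   `ec50_pM`; defaults to the shipped cAMP-assay potency panel for the
#'   GIPR-targeting peptide C803-GIP and its gallium-loaded form across the
#'   GIPR, GLP-1R and GCGR in human, non-human-primate and rat receptors.
#' @return Data frame of potencies.
#' @export
read_potency_table <- function(path = NULL) {
  path <- path %||% ref_file("c803gip_ec50.csv")
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("compound", "species", "receptor", "ec50_pM")
  miss <- setdiff(need, names(df))
  if (length(miss))
    pd_stop("schema_error", "potency table missing column(s): %s",
            paste(miss, collapse = ", "))
  if (any(df$ec50_pM <= 0))
    pd_stop("validation_error", "EC50 values must be positive")
  df
}

#' Fold selectivity between receptors
#'
#' `EC50(off-target) / EC50(target)`: how many-fold weaker the compound is
#' at the off-target receptor.
#'
#' @param potency Data frame from [read_potency_table()].
#' @param compound,species Row selectors.
#' @param target,offtarget Receptor labels.
#' @return Fold selectivity (dimensionless).
#' @export
selectivity_ratio <- function(potency, compound, species, target, offtarget) {
  pick <- function(receptor) {
    i <- potency$compound == compound & potency$species == species &
      potency$receptor == receptor
    if (sum(i) != 1L)
      pd_stop("lookup_error", "no unique EC50 for (%s, %s, %s)",
              compound, species, receptor)
    potency$ec50_pM[i]
  }
  pick(offtarget) / pick(target)
}
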