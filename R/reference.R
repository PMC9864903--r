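#' Anthropomorphic reference phantom
#'
#' Organ masses and whole-body mass of an adult reference phantom, used to
#' extrapolate rodent SUVs to human organ fractions and to mass-weight the
#' ICRP-60 remainder tissues. Built-ins (`"adult_male"`, `"adult_female"`)
#' ship as editable CSV/JSON files under `inst/extdata` and follow the
#' OLINDA-style adult phantom conventions; substitute your own masses by
#' constructing a phantom directly.
#'
#' @param sex `"male"` or `"female"`.
#' @param body_mass_kg Whole-body mass in kg.
#' @param organ_masses Named numeric vector, organ -> mass in grams. Names
#'   are lower-cased canonical organ labels (e.g. `"kidneys"`,
#'   `"uli wall"`, `"red marrow"`, `"blood"`).
#' @param remainder_organs Character vector of organs making up the ICRP-60
#'   remainder tissue.
#' @return An object of class `"phantom"`.
#' @export
phantom <- function(sex = c("male", "female"), body_mass_kg, organ_masses,
                    remainder_organs = character()) {
  sex <- match.arg(sex)
  if (!is_number(body_mass_kg) || body_mass_kg <= 0)
    pd_stop("validation_error", "body_mass_kg must be positive")
  organ_masses <- setNames(as.numeric(organ_masses),
                           canonical_organ(names(organ_masses)))
  if (any(!is.finite(organ_masses)) || any(organ_masses <= 0))
    pd_stop("validation_error", "all organ masses must be positive")
  if (sum(organ_masses) > 1000 * body_mass_kg)
    pd_stop("validation_error",
            "sum of organ masses (%.0f g) exceeds body mass (%.0f g)",
            sum(organ_masses), 1000 * body_mass_kg)
  remainder_organs <- canonical_organ(remainder_organs)
  missing <- setdiff(remainder_organs, names(organ_masses))
  if (length(missing))
    pd_stop("validation_error", "remainder organs missing from masses: %s",
            paste(missing, collapse = ", "))
  structure(list(sex = sex, body_mass_kg = body_mass_kg,
                 organ_masses = organ_masses,
                 remainder_organs = remainder_organs),
            class = "phantom")
}

#' @export
print.phantom <- function(x, ...) {
  cat(sprintf("<phantom> adult %s, %.1f kg, %d organs (%d remainder)\n",
              x$sex, x$body_mass_kg, length(x$organ_masses),
              length(x$remainder_organs)))
  invisible(x)
}

#' ICRP-style tissue weighting factors
#'
#' Holds the named tissue weighting factors w_T, the remainder weight and the
#' conventions needed to apply them to an organ equivalent-dose table: the
#' ULI/LLI split standing in for the colon, and the surrogate organ used for
#' the esophagus (OLINDA 1.1 convention: thymus). The built-in `"icrp60"`
#' set sums to exactly 1.
#'
#' @param weights Named numeric vector of w_T for the named tissues
#'   (`"gonads"`, `"red marrow"`, `"colon"`, `"lungs"`, `"stomach wall"`,
#'   `"urinary bladder wall"`, `"breasts"`, `"liver"`, `"esophagus"`,
#'   `"thyroid"`, `"skin"`, `"osteogenic cells"` for ICRP-60).
#' @param remainder_weight Weight of the remainder tissue.
#' @param colon_split Length-2 numeric `(fraction ULI, fraction LLI)`.
#' @param esophagus_surrogate Organ whose dose stands in for the esophagus.
#' @return An object of class `"tissue_weights"`.
#' @export
tissue_weights <- function(weights, remainder_weight,
                           colon_split = c(0.57, 0.43),
                           esophagus_surrogate = "thymus") {
  weights <- setNames(as.numeric(weights), canonical_organ(names(weights)))
  if (any(weights < 0) || remainder_weight < 0)
    pd_stop("validation_error", "tissue weights must be non-negative")
  total <- sum(weights) + remainder_weight
  if (abs(total - 1) > 1e-9)
    pd_stop("validation_error",
            "tissue weights must sum to 1, got %.12g", total)
  if (length(colon_split) != 2L || abs(sum(colon_split) - 1) > 1e-9)
    pd_stop("validation_error", "colon_split must be two fractions summing to 1")
  structure(list(weights = weights, remainder_weight = remainder_weight,
                 colon_split = colon_split,
                 esophagus_surrogate = canonical_organ(esophagus_surrogate)),
            class = "tissue_weights")
}

#' S-value table for MIRD organ dose calculation
#'
#' Maps (target organ, source organ) pairs to S-values in mGy/(MBq h) for a
#' given nuclide and phantom. A self-dose entry (target == source) must be
#' present for every organ appearing as a target.
#'
#' @param entries Data frame with columns `target`, `source`,
#'   `s_mGy_per_MBq_h`.
#' @param nuclide Nuclide label the table applies to.
#' @param sex Phantom sex the table applies to.
#' @return An object of class `"svalue_table"`.
#' @seealso [selfdose_svalues()] for the shipped demonstration builder.
#' @export
svalue_table <- function(entries, nuclide = "Ga-68", sex = "male") {
  need <- c("target", "source", "s_mGy_per_MBq_h")
  miss <- setdiff(need, names(entries))
  if (length(miss))
    pd_stop("schema_error", "S-value table missing column(s): %s",
            paste(miss, collapse = ", "))
  entries$target <- canonical_organ(entries$target)
  entries$source <- canonical_organ(entries$source)
  if (any(entries$s_mGy_per_MBq_h < 0))
    pd_stop("validation_error", "S-values must be non-negative")
  targets <- unique(entries$target)
  selfed <- entries$target[entries$target == entries$source]
  no_self <- setdiff(setdiff(targets, "remainder"), selfed)
  if (length(no_self))
    pd_stop("validation_error", "no self-dose entry for target(s): %s",
            paste(no_self, collapse = ", "))
  structure(list(entries = entries[, need], nuclide = nuclide, sex = sex),
            class = "svalue_table")
}

#' Demonstration self-dose S-value table
#'
#' Builds a non-penetrating self-dose approximation
#' `S(T <- T) = k * E_np / m_T` from a phantom's organ masses and a
#' nuclide's mean non-penetrating energy per decay
#' (`k = 3.6e9 decays/(MBq h) * 1.602e-13 J/MeV`, dose in mGy). Cross-organ
#' photon terms are zero, so this table is for demonstration and plumbing
#' tests only, **not** for clinical dose estimates; supply a full S-value
#' table as CSV for real use. The `"remainder"` source is included with zero
#' dose to every target (its non-penetrating energy is absorbed in
#' unmodelled tissue).
#'
#' @param phantom A [phantom()].
#' @param nuclide A [radionuclide()] with `np_energy_mev` set.
#' @param sources Organs to include (default: all phantom organs except
#'   blood, which is a kinetic pool rather than a dose source).
#' @return An [svalue_table()].
#' @export
selfdose_svalues <- function(phantom, nuclide,
                             sources = setdiff(names(phantom$organ_masses), "blood")) {
  if (is.na(nuclide$np_energy_mev))
    pd_stop("validation_error", "nuclide has no np_energy_mev")
  m <- phantom$organ_masses[sources]
  # 1 MBq h = 3.6e9 decays; MeV -> J; per g -> per kg -> mGy
  k <- 3.6e9 * 1.602176634e-13 * 1e6
  ent <- data.frame(target = sources, source = sources,
                    s_mGy_per_MBq_h = k * nuclide$np_energy_mev / as.numeric(m))
  ent <- rbind(ent, data.frame(target = sources, source = "remainder",
                               s_mGy_per_MBq_h = 0))
  svalue_table(ent, nuclide = nuclide$name, sex = phantom$sex)
}

ref_file <- function(file) {
  system.file("extdata", file, package = "petdosim", mustWork = TRUE)
}

#' Organ-name alias table
#'
#' Editable mapping from dissected-sample organ labels (e.g. `"kidney"`,
#' `"bone"`, `"urinary bladder (rinsed)"`) to canonical phantom organ names
#' (`"kidneys"`, `"osteogenic cells"`, `"urinary bladder wall"`).
#'
#' @param path Optional CSV with columns `alias`, `canonical`; defaults to
#'   the shipped table.
#' @return Named character vector, alias -> canonical.
#' @export
organ_aliases <- function(path = NULL) {
  path <- path %||% ref_file("organ_aliases.csv")
  df <- read.csv(path, stringsAsFactors = FALSE)
  setNames(canonical_organ(df$canonical), canonical_organ(df$alias))
}

#' Load built-in or on-disk reference data
#'
#' Single entry point for the reference data the dosimetry chain consumes:
#' nuclide constants, phantom organ masses, tissue weighting factors and
#' S-value tables.
#'
#' Built-in names: `nuclide = "ga68"`; `phantom = "adult_male"`,
#' `"adult_female"`; `weights = "icrp60"`; `svalues = "selfdose_male"`,
#' `"selfdose_female"` (demonstration self-dose tables, see
#' [selfdose_svalues()]). Any other value is treated as a path to a file in
#' the documented format (JSON for nuclide/weights, CSV for S-values).
#'
#' @param kind One of `"nuclide"`, `"phantom"`, `"weights"`, `"svalues"`.
#' @param source Built-in name or file path.
#' @return The corresponding object ([radionuclide()], [phantom()],
#'   [tissue_weights()] or [svalue_table()]).
#' @examples
#' ga68 <- load_reference_data("nuclide", "ga68")
#' w <- load_reference_data("weights", "icrp60")
#' sum(w$weights) + w$remainder_weight  # exactly 1
#' @export
load_reference_data <- function(kind = c("nuclide", "phantom", "weights", "svalues"),
                                source) {
  kind <- match.arg(kind)
  builtins <- list(nuclide = "ga68",
                   phantom = c("adult_male", "adult_female"),
                   weights = "icrp60",
                   svalues = c("selfdose_male", "selfdose_female"))
  is_builtin <- source %in% builtins[[kind]]
  if (!is_builtin && !file.exists(source))
    pd_stop("lookup_error",
            "unknown %s '%s'; built-ins: %s (or pass an existing file path)",
            kind, source, paste(builtins[[kind]], collapse = ", "))
  switch(kind,
    nuclide = {
      path <- if (is_builtin) ref_file("nuclide_ga68.json") else source
      j <- jsonlite::read_json(path, simplifyVector = TRUE)
      radionuclide(j$name, j$half_life_min, j$np_energy_mev %||% NA_real_,
                   j$branching %||% NA_real_)
    },
    phantom = {
      stem <- if (is_builtin) source else
        pd_stop("lookup_error",
                "phantoms load from built-ins ('adult_male', 'adult_female'); construct phantom() directly for custom masses")
      masses <- read.csv(ref_file(paste0("phantom_", stem, "_masses.csv")),
                         stringsAsFactors = FALSE)
      meta <- jsonlite::read_json(ref_file(paste0("phantom_", stem, "_meta.json")),
                                  simplifyVector = TRUE)
      phantom(meta$sex, meta$body_mass_kg,
              setNames(masses$mass_g, masses$organ),
              remainder_organs = meta$remainder_organs)
    },
    weights = {
      path <- if (is_builtin) ref_file("tissue_weights_icrp60.json") else source
      j <- jsonlite::read_json(path, simplifyVector = TRUE)
      tissue_weights(unlist(j$weights), j$remainder_weight,
                     colon_split = j$colon_split,
                     esophagus_surrogate = j$esophagus_surrogate)
    },
    svalues = {
      if (is_builtin) {
        sex <- sub("selfdose_", "", source)
        selfdose_svalues(load_reference_data("phantom", paste0("adult_", sex)),
                         load_reference_data("nuclide", "ga68"))
      } else {
        df <- read.csv(source, stringsAsFactors = FALSE)
        svalue_table(df)
      }
    })
}
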