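---
title: "Methods: from ex vivo counts to predicted human dose"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from ex vivo counts to predicted human dose}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(petdosim)
```

petdosim implements the computational chain used to evaluate a preclinical
PET radioligand from ex vivo data — here motivated by a Ga-68-labelled
GIPR-targeting peptide, but applicable to any short-lived tracer counted in
dissected tissue. This vignette explains each model, its assumptions, the
tunable parameters, and the numerical choices, in the order the pipeline
runs them.

## Biodistribution: SUVs and blocking

Each gamma-counter sample is converted to a standardized uptake value

$$\mathrm{SUV} = \frac{A_\mathrm{tissue}/m_\mathrm{tissue}}
{A_\mathrm{injected}/m_\mathrm{body}},$$

a dimensionless concentration ratio: SUV = 1 means the tissue holds the
whole-body average concentration. Activities are either decay-corrected to
the injection time (the usual reporting convention) or left as measured
("SUV$_A$"). Because the two conventions feed different downstream stages —
reporting uses corrected values, residence-time integration *requires*
uncorrected ones — every curve and dataset carries an explicit
`decay_corrected` flag, and stages that need a particular state raise a
state error instead of guessing. `decay_transform()` converts between the
two with $e^{\pm\lambda t}$, $\lambda = \ln 2 / T_{1/2}$; the round trip is
an exact identity.

Receptor specificity in vivo is assessed by co-injecting excess unlabelled
peptide: `blocking_effect()` reports
$100\,(1 - \bar{S}_\mathrm{blocked}/\bar{S}_\mathrm{baseline})$ with a
one-way ANOVA p-value (for two groups this equals the pooled t-test,
$F = t^2$). No multiple-testing correction is applied across organs — the
output notes this — because organ-wise screening at this stage is
descriptive, not confirmatory.

## Non-compartmental pharmacokinetics

`pk_nca()` follows standard NCA conventions. The terminal half-life is
$\ln 2 / |\hat\beta|$ from a least-squares regression of log concentration
on time; the default window is the last three positive, uncensored samples,
overridable because sparse designs often make the window a judgement call.
AUC$_\mathrm{inf}$ uses the linear trapezoid over the observed span (a
$(0, 0)$ anchor is prepended for extravascular dosing; intravenous profiles
back-extrapolate $C_0$ from the first two positive points) plus a
$C_\mathrm{last}/k$ exponential tail. Clearance is dose/AUC with unit
conversion (mg/kg per h·ng/mL → L/h/kg ×1000).

Below-LOD samples need a decision. The subcutaneous design this package
emulates assigns such samples *zero* and treats them as observed; the
default `censored_zero = "observed"` reproduces that convention exactly —
the zero enters the trapezoid and suppresses the tail. The alternative
(`"exclude"`) drops censored points and extrapolates from the last positive
sample; the two differ by the triangle to zero versus the exponential tail,
and both are reported with the extrapolated fraction so the choice is
auditable.

## Saturation binding and internalization

Specific binding is the blocking-arm subtraction total − non-specific
(negatives clamped to zero with a count, since proportional noise can push
low-concentration differences negative). `saturation_fit()` fits the
one-site hyperbola $B(C) = B_\mathrm{max} C/(K_d + C)$ by nonlinear least
squares (Levenberg–Marquardt). Starting values are deterministic and
data-driven — $B_{\mathrm{max},0}$ is the largest mean bound value,
$K_{d,0}$ the concentration at half of it by interpolation — so repeated
fits are reproducible without user tuning. A fitted $K_d$ far outside the
assayed concentration range triggers an extrapolation warning. When no
blocking arm exists, `fit_ns = TRUE` adds a free linear non-specific term
to a total-binding fit; this is a weaker design and is kept opt-in.

Internalization counting data are normalized to percent of the added dose
per million cells; the internalized share of total is left undefined (not
NaN) when the total is zero, as at the $t = 0$ sample.

## Autoradiography calibration

Pixel count densities convert to activity densities through the co-exposed
reference droplet of known activity:
$\mathrm{Bq/mm^2} = (\mathrm{counts/mm^2}) \times
(A_\mathrm{ref}/\mathrm{area}_\mathrm{ref}) / (\mathrm{counts/mm^2})_\mathrm{ref}$,
then to molar density by the molar activity (Bq/fmol). The chain is linear
in counts, so exposure time cancels — the reference droplet absorbs the
integration constant. An optional background region is subtracted from both
the target and the reference density, which makes a spatially uniform
background cancel exactly.

## Dosimetry: the MIRD chain

The rat-to-human extrapolation assumes the *relative* biodistribution
transfers across species: the fraction of injected activity in a human
organ is taken as

$$f_\mathrm{organ}(t) = \mathrm{SUV}_A(t)\,
\frac{m_\mathrm{organ}\,[\mathrm{g}]}{1000 \times m_\mathrm{body}\,[\mathrm{kg}]},$$

i.e. the published organ-per-body mass normalization written as a
dimensionless fraction (the printed form of this relation omits the unit
constant; consistent units make it a percent/100). Inputs must be flagged
decay-uncorrected.

Residence times integrate $f(t)$ to infinity: linear trapezoid over the
sampled span with $f(0) = 0$ prepended, then a tail from a
single-exponential least-squares fit to the last three points (the point
count is configurable; three is the smallest count that fits a rate with a
residual check). Two safeguards apply:

* if the fitted tail rate is *slower* than physical decay — apparent
  accumulation, as in an excreting kidney — the tail is clamped to
  $\lambda_\mathrm{phys}$, the conservative standard practice, and the
  clamp is annotated per organ;
* a failed fit falls back to physical decay with a warning annotation.

Red marrow uses the blood-volume model: marrow concentration = blood
concentration × RMBLR (default 1.0, configurable; the literature offers
values near 1 for small peptides, and the model is linear in the ratio so
sensitivity analysis is trivial). The remainder term defaults to
`no_excretion`: remainder = $T_{1/2}/\ln 2 - \sum_\mathrm{organs} \tau$,
clamped at zero. This is deliberately conservative — the tracer *is*
excreted in urine, but without a measured whole-body or excreta curve the
no-excretion construction bounds the missing activity from above; a
`whole_body_curve` mode accepts a measured whole-body residence time
instead.

Organ doses follow the MIRD schema $D(T) = \sum_S \tau_S\, S(T \leftarrow S)$.
S-value libraries are proprietary to established dosimetry software, so the
package treats them as data: any CSV of (target, source, S) entries loads
as a first-class table. The shipped builder `selfdose_svalues()` produces a
*non-penetrating self-dose approximation* ($S = k\,E_\mathrm{np}/m_T$,
cross-organ terms zero, the remainder source contributing nothing) that is
clearly labelled for demonstration and plumbing tests — it is not a
clinical dose model, and the per-organ doses it yields are not comparable
to published tables.

### ICRP-60 effective dose

`effective_dose()` applies the ICRP-60 weighting factors with the
conventions of OLINDA-era practice: colon = 0.57 ULI + 0.43 LLI; the
esophagus (no phantom organ) takes the thymus dose as surrogate; gonads are
testes or ovaries by phantom sex; and the 0.05 remainder weight follows the
split rule — if the hottest remainder organ out-doses every named tissue
(here, the kidney by a factor ~20), it receives half the remainder weight
and the mass-weighted mean of the other remainder organs the other half.
The remainder set is adrenals, brain, small intestine, kidneys, muscle,
pancreas, spleen and thymus; when the thymus serves as esophagus surrogate
it is excluded from the remainder mean (its mass share makes this a
sub-ppm effect, but double counting is avoided on principle). Applying
this procedure to the shipped published organ-dose table reproduces the
published effective doses to within about 1% for both sexes — residual
differences reflect unprinted details of the original software's remainder
and phantom conventions, which is why the package's own check uses a 5%
band. Contributions are returned per tissue and sum exactly to the total.

The phantom organ masses shipped with the package follow OLINDA-style
adult male (73.7 kg) and female (56.8 kg) conventions. The original
analysis does not print the masses it used, so these are a documented,
editable choice (CSV under `inst/extdata/`), not a reproduced fact; they
enter the effective dose only through the remainder mass weighting, which
muscle dominates.

## Synthetic data: what it emulates, and what not

The generators reproduce the *statistical structure* of each assay so the
whole pipeline is testable without animal data; their defaults are the
study conditions where stated, and labelled illustrative otherwise.

* **Biodistribution** (`simulate_biodistribution()`): the eight-time-point
  (5–180 min), two-animals-per-point complete-dissection design. Washout
  organs follow a double-exponential $F(e^{-k_w t} - e^{-k_u t})$
  normalized to peak $F$; the kidney follows a monotone accumulation
  $F(1 - e^{-k_u t})$. Default kinetics are illustrative but constrained
  by the reported qualitative pattern: liver SUV < 1 at 5 min with ~50%
  washout at 1 h, fast blood clearance (appearance half-time ~1.4 min),
  kidney SUV rising through 180 min, and peak fractions summing below 1 so
  complete-dissection activity conservation holds. Both organ models have
  closed-form decay-weighted integrals, so the truth record scores any
  downstream residence-time estimate; at the 8-point design the pipeline
  recovers the analytic values to ~1%. Noise is mean-preserving lognormal
  (positive support, CV 10% by default).
* **Plasma PK** (`simulate_plasma_pk()`): one-compartment first-order
  absorption sampled at 3, 6, 9.6, 19.8, 30, 60, 120, 240 min, with
  below-LOD samples assigned zero and flagged — including the 240-min
  point under the default LOD of 5 ng/mL, matching the emulated design.
  Defaults: dose 1 mg/kg, elimination t½ 0.38 h, clearance 0.73 L/h/kg,
  absorption t½ 0.1 h.
* **Saturation assay** (`simulate_saturation_assay()`): seven
  concentrations 0.3–300 nM in triplicate, Kd 18.3 nM, Bmax 2.4
  pmol/Mcells, shallow linear non-specific component, 10% proportional
  (lognormal) noise.
* **Internalization** (`simulate_internalization()`): surface binding
  approaching equilibrium at rate $k_s$ while feeding an internal pool at
  rate $k_\mathrm{int}$ (zero at 4 °C), giving ~60–85 %ID/Mcells total
  over 2 h with ~40% internalized at 37 °C.
* **Autoradiogram** (`simulate_autoradiogram()`): square pellets and a
  reference droplet on an 80×80 grid, Poisson counting noise over a
  uniform background.

What the generators do **not** emulate: inter-animal kinetic heterogeneity
(noise is attached to measurements, not rate constants), plasma protein
binding and metabolite formation, partial-volume and scatter effects of
image-derived data, chromatographic impurities, and spatial autoradiogram
artefacts (non-uniform screen response, bleed-over). Passing recovery tests
therefore demonstrate that the *estimators are correct for their models*,
not that the models capture every feature of real data.

All generators take an integer seed, use a private RNG stream, restore the
caller's RNG state, and are bit-reproducible for equal seeds.

## Numerical choices and degenerate inputs

* Times are minutes internally; PK and dosimetry outputs report hours
  (residence times in MBq·h/MBq ≡ h).
* Linear (not log) trapezoid throughout, matching the named integration
  rule of the emulated analysis; quadrature error is $O(h^2)$, and the
  property suite bounds trapezoid overshoot of the physical residence-time
  limit by the standard $(\lambda h_\mathrm{max})^2/12$ relative bound.
* Terminal slopes within $10^{-12}$/min of zero count as "no decline" and
  raise an error rather than returning absurd half-lives.
* All-zero inputs: an all-zero fraction curve has τ = 0 (not an error); an
  all-zero plasma profile returns AUC 0 with a warning; a zero
  internalization total yields an undefined (NA) share.
* Validation is row-addressed and classed (`schema_error`,
  `validation_error`, `state_error`, …); negative activities or masses are
  never silently coerced.
* Problem sizes in the test suite (dense PK grids of ~1000–6000 points,
  200 simulated assays for the recovery study, 80×80 autoradiogram grids)
  were chosen as the smallest sizes at which the asymptotic claims they
  check are comfortably inside tolerance.

## Known limitations

* The shipped self-dose S-value approximation ignores photon cross-dose;
  per-organ absorbed doses from `dosimetry_report()` with the default
  table are structural placeholders until a real S-value CSV is supplied.
  The ICRP-60 weighting stage, by contrast, is exact given a dose table.
* The rat-to-human mass-ratio extrapolation inherits the usual caveats
  (species differences in receptor density and excretion are not
  modelled).
* EC50 potencies are consumed as inputs (selectivity ratios); fitting
  concentration–response curves from raw functional data is out of scope.
* Image-derived (PET volume) SUVs, DICOM/PMOD ingestion, and voxel
  dosimetry are out of scope; tabulated time–activity data are the
  ingestion boundary.
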