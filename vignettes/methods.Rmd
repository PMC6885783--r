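---
title: "Methods: photon attenuation and aerosol-immersion dosimetry for protective clothing"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: photon attenuation and aerosol-immersion dosimetry for protective clothing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ppeshield)
```

## Scope

`ppeshield` characterises personal protective equipment (PPE) whose
shielding layers contain heavy metals.  It covers the full desk-scale
computational chain used in such studies:

1. narrow-beam spectral attenuation analysis - from paired open-beam and
   sample gamma spectra to relative penetration $P$, attenuation
   $A = 1 - P$, measured mass attenuation coefficients $\mu/\rho$ and
   lead equivalents $t_\mathrm{Pb}$;
2. seeded Monte Carlo photon transport - a slab mode with an
   uncollided-photon tally, and a chamber mode with per-organ energy
   deposition on a stylized phantom;
3. effective-dose assembly under a dispersed radioactive aerosol source
   term with ICRP 103 tissue weighting, including an empirical
   beta-transmission model;
4. a synthetic spectrum generator that stands in for the laboratory
   measurements, so the whole chain runs without any external data.

## Bundled photon interaction data

Elemental tables (15 elements from H to Pb) ship as versioned CSVs with
partial mass interaction coefficients (photoelectric, incoherent,
coherent, pair) on a common 10--3000 keV grid.  They are produced once by
`data-raw/make_xs_tables.R` from a compact analytic photoatomic model:

* **Incoherent**: the exact free-electron Klein-Nishina total cross
  section times $Z$.  No incoherent scattering function is applied; the
  binding correction it would bring matters only below ~30 keV where the
  photoelectric term dominates in the high-$Z$ shielding materials of
  interest.
* **Photoelectric**: Stobbe-type hydrogen-like shell cross sections
  (K, L, M) with screened charge $Z - 0.3$, exact near-threshold Coulomb
  factors, and a relativistic bridge factor $(1 + aE/m_ec^2)^{5/2}$ that
  restores the known $1/E$ high-energy behaviour.  Shell amplitudes and
  $a$ were calibrated once, by least squares, against a short set of
  published total-attenuation anchor values for lead and water.
* **Coherent**: Thomson scattering with an exponential-screening atomic
  form factor whose screening momentum scales as $Z^{1/3}$; the scale is
  part of the same calibration.
* **Pair production**: a two-parameter $Z^2$-scaled fit anchored on lead
  above the 1022 keV threshold.

Absorption edges are represented as duplicated grid abscissae carrying
the below/above-edge values; interpolation is log-log linear, and an
evaluation exactly at an edge deterministically returns the above-edge
branch.  The "total" coefficient includes coherent scattering
(attenuation-with-coherent), the correct convention for a narrow-beam
geometry in which any interaction removes the photon from the beam.

The calibrated model reproduces the anchor set to a few percent across
100--3000 keV and to ~10-15% in the soft 20--100 keV region around the
lead K-edge; quantities built from coefficient *ratios* (notably lead
equivalents, where an overall scale cancels) are insensitive to the
residual scale error.  Accuracy is enforced by tests against
independently re-read table values and closed-form oracles.

## Spectral analysis

The peak-area algorithm is deliberately simple and deterministic: the
region of interest spans the catalogued centroid $\pm 1.5\,$FWHM; the
background is a straight line through the mean counts of two flanking
bands of width 1 FWHM placed directly outside the ROI; the net-area
variance combines the Poisson variance of the gross counts with the
variance of the background estimate.  "Significant" peaks are catalogued
lines with emission probability at least 1%, no other catalogued line
within 3 FWHM, a fully contained ROI, and an open-beam relative
uncertainty below 1% (the acquisition criterion used on the bench).

Relative penetration is the live-time-corrected net-area ratio; its
uncertainty follows from the two relative area uncertainties in
quadrature.  Values slightly above 1 (possible for thin samples under
Poisson noise) are accepted up to $3\sigma$ and clipped to 1 for
log-domain quantities, with a warning.

The mean lead equivalent averages per-energy values with equal weights,
excluding energies within 2 FWHM of any K absorption edge of the sample's
elements or of lead, and reports the standard deviation across energies
as its spread - matching how mean lead equivalents with
standard-deviation error bars are usually quoted.  Lead is converted with
the conventional $\rho_\mathrm{Pb} = 11.35\ \mathrm{g\,cm^{-3}}$.

## Synthetic spectra

The generator emulates a collimated point-source bench: expected detected
events per line are
$\lambda = A\, y\, \varepsilon(E)\, g\, t_\mathrm{live}\, P_\mathrm{abs}(E)$
with a smooth log-normal full-energy-peak efficiency
$\varepsilon(E)$ and one calibrated geometry constant $g$ per detector
(the physical collimator stack is not ray-traced).  A fixed fraction of
each line's events feeds a flat continuum below the peak; the rest form a
Gaussian peak of the detector's FWHM $= a\sqrt{E} + b$.  Channel contents
are Poisson; every call requires an explicit seed and records a truth
table of sampled per-line counts, so generator bookkeeping is exactly
auditable.  Two generic detector models are bundled: a scintillator class
(~3% FWHM at 662 keV) and a high-resolution semiconductor class (~0.2%);
they are plausible stand-ins, not calibrations of any particular
instrument.  Default plans (20 MBq, 600 s) sit inside the 9.5--40 MBq and
120--1800 s bench ranges and satisfy the sub-percent peak-uncertainty
criterion.

What the generator does *not* emulate - escape and sum peaks, pile-up,
dead time beyond live/real bookkeeping, detector efficiency drift -
bounds what passing tests show about real spectra: the pipeline is
validated for isolated full-energy peaks on smooth continua, which is
the regime the narrow-beam method is designed for.  Compositions of the
proprietary shielding layers were never published; the fixtures declare
assumed, shielding-equivalent stand-ins (flagged `assumed`) in one
editable YAML file, with the catalogued areal densities.

## Monte Carlo photon transport

The engine implements analog photon transport with photoelectric
absorption, free-electron Klein-Nishina incoherent scattering (standard
two-branch rejection sampling), coherent scattering with the Thomson
angular form (direction change only), and pair production above
1022 keV depositing $E - 1022$ keV locally and emitting two opposed
511 keV annihilation photons.  Secondary electrons deposit locally
(collision-kerma approximation) - their ranges (a few mm in tissue at
these energies) are small against organ dimensions.  Bremsstrahlung from
secondaries is therefore omitted; this is a declared divergence from
full coupled photon-electron transport and part of why chamber results
carry wide acceptance bands.  The low-energy photon cutoff is 10 keV;
sub-cutoff photons deposit on the spot.

**Narrow-beam mode.**  The uncollided-fraction tally depends only on
whether each history interacts anywhere in the stack, so analog
transport reduces *exactly* to Bernoulli trials with survival
$\exp(-\sum_i (\mu/\rho)_i d_i)$; the implementation samples them in
batches (20 by default) and reports the batch-based relative standard
error.  The default budget of $2\times 10^6$ histories reaches the 0.1%
precision used for such tallies.

**Chamber mode.**  The 250 x 200 x 200 cm gas-tight chamber is air
filled; the stylized phantom stands at its centre.  Walls act through a
precomputed single-scatter concrete albedo (normal-incidence
approximation, 30 log-spaced energies x 20 exit-angle bins): each wall
entry either returns one Compton-shifted backscattered photon or absorbs
the history.  A returning photon that strikes a wall again receives the
same treatment; this per-entry reading keeps the energy audit exact.
Garments are conformal shells of the catalogued areal density over the
covered body regions; crossings apply slant-path attenuation
$1 - \exp(-\mu d / |\cos\theta|)$ (slant capped at 10 to avoid grazing
blow-up) and sample the interaction physics of the garment material.

The RNG is a counter-based PCG32 with one independent substream per
history and per source, so identical (scene, config, seed) runs are
bit-identical, and paired with/without-garment runs stay correlated for
histories whose transport never touches the garment - a substantial
variance reduction for small dose decreases, exploited by forming
decreases pairwise per batch.

Tallies are analog collision deposits by default; an optional
track-length expected-value estimator scores
$E\, f_\mathrm{dep}(E)\, \mu\, \ell$ along organ chord lengths (with
$f_\mathrm{dep}$ the mean deposited fraction per collision, precomputed
from the partial coefficients and the Klein-Nishina mean scattered
fraction).  It is unbiased and markedly lowers the variance for small
organs such as the adrenals or thyroid; the energy-conservation audit
applies to the analog mode, where bookkeeping is exact by construction.

## Stylized phantom

The phantom is a simplified MIRD-style stylized adult: elliptic-cylinder
trunk (40 x 20 cm section, 70 cm tall), elliptic-cylinder head, two
cylindrical legs, a 2 mm skin shell, and 17 organ regions placed as
ellipsoids or elliptic cylinders at stylized positions with volumes near
reference organ masses (homogeneous soft tissue, 1.04 g cm^-3; organs
are tally regions, not separate materials, so lungs are not deflated in
density).  Testes and genitalia sit in the lower front trunk so that a
torso vest covers them, matching how vests shield the gonads.  Organs
are pairwise non-overlapping (verified by sampling in the test suite via
region lookup consistency).  This is an intentional simplification of
the full stylized-phantom equation set; organ-level dose decreases are
therefore compared with tabulated reference values only within +/- 10
percentage-point bands.

Tissues without an explicit region are completed by documented
approximations: red bone marrow and bone surface take the trunk+legs
average non-organ tissue dose, breast the skin-shell dose, salivary
glands the head average, muscle the whole-body non-organ average.

## Source term and dose assembly

The aerosol source term puts 90% of the activity uniformly in the air
(rejecting points inside the body) and splits the remaining 10% between
the chamber walls and the outer garment surface at equal activity per
unit area - the most literal reading of equal surface activity; since
the wall area (28 m^2) dwarfs the clothed-body area (~1.6 m^2), the
garment-surface source is small.  Doses are kept in
Sv per Bq s (per unit time-integrated activity); decreases are ratios,
so the normalisation cancels.

Equivalent doses divide deposited energy by the modelled region mass
(radiation weighting factor 1 for photons and electrons); the effective
dose applies the ICRP 103 weights, which sum to 1 exactly, with the
remainder as the arithmetic mean of its available member organs.  The
torso effective dose restricts the weighted sum to the 15 torso organs
with *un-renormalised* weights - torso and whole-body values then share
one scale, and ratios are unaffected by the choice.

**Beta dosimetry.**  Betas are treated only through the dominant
pathway: air-immersion surface dose to skin, computed per branch as half
the infinite-cloud equilibrium dose scaled by a finite-chamber factor
$\min(V_\mathrm{chamber} / \tfrac{4}{3}\pi R_\mathrm{air}^3,\, 1)$ with
$R_\mathrm{air}$ the Katz-Penfold range at the endpoint energy, then
multiplied by the empirical transmission
$\exp(-17 (E_\mathrm{max}/\mathrm{MeV})^{-1.14} d)$ of the covering
garment stack.  The testes/genitalia region additionally sees the organ
geometry (a surface-shell fraction $\lambda A/V$ with $\lambda$ the
empirical beta attenuation length in tissue) and the overlying 2 mm skin
shell, which absorbs most beta energy before it reaches the organ - an
organ-averaged testes dose is then photon-dominated, as coupled
photon-electron reference calculations find.  Betas from wall and
garment-surface deposits are neglected.

## Numerical choices and degenerate inputs

* Log-log interpolation everywhere on cross-section grids; no
  extrapolation - out-of-range energies are errors.
* Edge evaluation returns the above-edge branch; the edge-exclusion
  window for mean lead equivalents is $2\,$FWHM at the edge energy.
* Zero areal density is a valid absorber (penetration exactly 1, zero
  tally variance); zero open-beam rate, empty point sets and missing
  organs raise the documented errors rather than propagating NaN.
* Noise-free generator mode keeps exact expected (non-integer) channel
  contents so that round-trip identities hold to numerical precision.
* Batch statistics use at least 10 batches; relative standard errors of
  zero-variance tallies are reported as 0.

## Problem sizes

The test suite runs narrow-beam tallies at $10^4$ to $8\times 10^5$
histories, chamber transport at $5\times 10^3$ to $3\times 10^5$
histories per (line, source) run, and 200-replicate generator
calibrations; the acceptance script uses the default $2\times 10^6$
narrow-beam budget and $5\times 10^5$ histories per chamber run (about
half a minute in total on one core).  These sizes were chosen as the
smallest that leave the batch standard errors well inside the acceptance
bands; all quantities scale to larger budgets by the verified
$1/\sqrt{N}$ law.

## Known limitations

* No coupled electron transport, no bremsstrahlung, no incoherent
  scattering function or coherent form-factor anisotropy beyond the
  Thomson shape - adequate for dose *ratios* at aerosol-relevant
  energies, not for absolute microdosimetry.
* The single-scatter wall albedo underestimates multiply-scattered
  room-return at low energies.
* The analytic photoatomic model is calibrated, not evaluated, data;
  applications needing evaluated-library fidelity should regenerate the
  tables from such a source (the CSV schema is the interface).
* Proprietary layer compositions are assumed; only their areal densities
  are measured quantities.
* The phantom has no arms; trunk-incident fluence is therefore slightly
  higher than for an arms-down human, which tends to strengthen torso
  garment effects within the stated bands.
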