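---
title: "Methods: pKa determination and supramolecular shifts by capillary electrophoresis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: pKa determination and supramolecular shifts by capillary electrophoresis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cepka)
```

## The measurement model

Capillary electrophoresis determines the acidity constant of a monoprotic
acid HA from the pH dependence of its electrophoretic mobility. The neutral
form does not migrate relative to the electroosmotic flow (EOF); the anion
does. With total and effective capillary lengths $L_{tot}$ and $L_{eff}$,
nominal voltage $U$, and migration times $t_{tot}$ (analyte) and $t_{eof}$
(neutral EOF marker), the electrophoretic mobility is

$$\mu_{ep} \;=\; \frac{L_{tot}\,L_{eff}}{U}\left(\frac{1}{t_{tot}} -
\frac{1}{t_{eof}}\right),$$

and for a monoprotic acid

$$\mu_{ep}(\mathrm{pH}) \;=\;
\frac{10^{-pK_a}}{10^{-pK_a} + 10^{-\mathrm{pH}}}\;\mu_{A^-}
\;=\; f(\mathrm{pH})\,\mu_{A^-},$$

where $f$ is the ionization fraction and $\mu_{A^-}$ the limiting mobility
of the fully deprotonated form. The p$K_a$ is the pH at the inflection
point of this sigmoid. Internally all quantities are SI (m, V, s,
m$^2$V$^{-1}$s$^{-1}$); run tables carry minutes and kV, as instrument
software reports them, and are converted exactly once at the I/O boundary.
Mobilities are kept *signed* throughout: $\mu_{ep} > 0$ exactly when the
analyte is detected before the EOF marker. Keeping signs (rather than a
magnitude convention) makes the closed-form two-values estimator and the
sigmoid fits work identically for co- and counter-electroosmotic
configurations.

When a neutral macrocyclic host (e.g. a cyclodextrin) is present, the
measured p$K_a$ is *apparent*: it characterizes the mixed population of
free and 1:1-complexed analyte. With binding constants $K_{HA}$ and
$K_{A^-}$ of the protonated and deprotonated forms and host concentration
$c$,

$$pK_a^{app} \;=\; pK_a^{free} +
\log_{10}\frac{1 + K_{HA}\,c}{1 + K_{A^-}\,c}.$$

Stronger binding of the protonated form raises the apparent p$K_a$. The
package estimates apparent values; decomposing them into complexation and
deprotonation thermodynamics would require the binding constants
themselves, which is out of scope.

## Three estimators

**Classical sigmoid fit** (`pka_fit(mu_ep ~ pH, data)`). Nonlinear least
squares of the mobility model with free $pK_a$ and $\mu_{A^-}$, using the
Levenberg–Marquardt algorithm. The protocol assumes 5–6 buffers spanning
the transition; the fit warns when the pH values do not bracket the fitted
p$K_a$. Starting values are data-driven — $pK_a^{(0)}$ is the pH of the
point whose mobility is closest to half the largest-magnitude mobility,
$\mu_{A^-}^{(0)}$ the mobility of that largest point — and on
non-convergence the start is perturbed by a fixed, deterministic sequence
of offsets (±0.4, ±0.8, +1.2 pH units, up to five restarts), so repeated
fits are reproducible. The neutral form's mobility is fixed at zero, which
is the physically motivated choice for a neutral HA; `free_baseline = TRUE`
frees it for coated capillaries with residual analyte–wall interaction.

**Two-values method** (`tvm_pka()`). The sigmoid model inverts in closed
form,

$$pK_a = \mathrm{pH} + \log_{10}\frac{\mu_{A^-} - \mu_{ep}}{\mu_{ep}},$$

so one partially ionizing buffer plus one fully ionizing buffer suffice.
This is a screening estimator: it is exact on noiseless data (the package
property-tests the inversion over a p$K_a$, pH grid) but inherits the full
error of two single measurements. Its standard error is obtained by
first-order propagation of the replicate standard deviations of the two
mobilities — the estimator has no residual degrees of freedom of its own.
The partial point is taken near half-ionization (around pH 4.6 for the
coumarins), the plateau from a high-pH buffer (pH 8); both are data, not
constants.

**Spectral β-ratio fit** (`pka_fit(beta ~ pH, method = "spectral")`). When
the host itself is charged (sulfated cyclodextrins, sulfonated
calixarenes), mobility no longer isolates the guest's ionization. If the
guest's absorption spectrum changes upon deprotonation, the ratio

$$\beta = \frac{A_1}{A_1 + A_2}$$

of absorbances at two wavelengths (270 and 300 nm by default, suiting
coumarin band pairs) is a concentration- and path-length-free ionization
observable, fitted as a Boltzmann sigmoid with *both* plateaus free (unlike
the mobility fit, the β plateaus are not known a priori). The slope factor
is fixed at the Henderson–Hasselbalch value for a monoprotic acid;
`free_slope = TRUE` exposes a Hill-type slope for diagnostic use. Note
that β is exactly affine in the ionization fraction only when the acid and
base forms have equal *total* absorbance over the wavelength pair; real
form pairs satisfy this approximately, and the residual distortion is
absorbed almost entirely by the free plateaus.

## The double correction strategy

Two systematic effects bias mobilities computed from nominal settings.

**Voltage ramping.** The voltage rises linearly to its nominal value over
the ramp time $t_{ramp}$ (0.1–0.2 min on common instruments), so the
time-averaged voltage over a species' migration is
$U_{av} = U(t_{tot} - 0.5\,t_{ramp})/t_{tot}$. Because analyte and EOF
marker migrate for different times, each species gets its own correction;
after simplification each reciprocal time in the mobility relation is
replaced by $1/(t - 0.5\,t_{ramp})$
(`mobility(..., ramping_correction = TRUE)`). Only the linear ramp shape is
supported — the factor 0.5 is the area of the ramp triangle.

**Joule heating.** Resistive heating raises the electrolyte temperature
above the coolant setpoint, more strongly in the non-thermostated inlet
section than in the cooled core, and *unequally across buffers* because
buffers of equal ionic strength but different composition draw different
currents. The package models the rise in each section as proportional to
the dissipated power per unit length, $\kappa\,UI/L_{tot}$, with one
coefficient per section supplied by the user (`sumet_parameters()`); this
preserves the structure of current-based two-section temperature estimation
while leaving the instrument- and capillary-specific constants to
calibration. The defaults (2.0 and 0.4 °C·m·W$^{-1}$) give a
length-weighted rise of 1–2 °C at 30 kV and ~50 µA in a 60 cm, 50 µm
capillary — the regime in which p$K_a$ corrections of a few hundredths of a
unit are expected. The effective temperature a mobility refers to is the
length-weighted average over the migration path,

$$T_{actual} = T_{inlet}\frac{L_{inlet}}{L_{eff}} +
T_{core}\frac{L_{eff}-L_{inlet}}{L_{eff}},$$

ignoring the section beyond the detector. The length weights are one
defensible choice among several; because the field strength (hence
velocity) is uniform along the capillary, residence-time weights coincide
with length weights, so the package exposes a general `w_inlet` override
rather than a separate "time" mode.

`run_dcs()` assembles the full procedure per system: (1) ramping-corrected
mobilities per run; (2) per-run $T_{actual}$ from the recorded currents;
(3) per-buffer polynomial models of mobility versus $T_{actual}$ (degree 2
by default, matching the mild curvature that viscosity and equilibrium
shifts impose over a 15–55 °C span; configurable, and an interpolating
degree can be chosen when exact node recovery is wanted); (4) mobilities
read off at shared temperatures of interest, flagged when extrapolated;
(5) sigmoid p$K_a$ fits per temperature, in three branches (uncorrected,
ramping-corrected, fully corrected); (6) Van't Hoff analysis per branch.
On the simulated validation scenario the ramping correction *lowers*
p$K_a$ and the thermal correction *raises* it — note this direction pattern
belongs to the counter-electroosmotic migration order (analyte after the
EOF marker); with the analyte ahead of the marker the ramp bias reverses
sign, which follows directly from the per-species form of the correction.

## Van't Hoff thermodynamics

`vant_hoff()` regresses $\ln K_a = -\ln(10)\,pK_a$ on $1/T$ (kelvin;
temperatures are stored in °C and converted only here):
$\ln K_a = \mathrm{slope}/T + \mathrm{intercept}$, with
$\Delta H^\circ = -R\cdot\mathrm{slope}$ reported in kJ·mol$^{-1}$. Two
entropy-flavoured quantities are returned: the SI entropy
$R\cdot\mathrm{intercept}$ and the dimensionless intercept itself
($\Delta S^\circ/R$). Published CE thermodynamic tables for these systems
print values that numerically match the *dimensionless intercept* under a
J·mol$^{-1}$·K$^{-1}$ heading — an apparent unit inconsistency the package
does not try to adjudicate. Both quantities are exposed under unambiguous
names (`dS_SI`, `entropic_term`), and comparisons with published tables use
the intercept. No activity-coefficient correction is applied; the
regressed p$K_a$ values are mixed-mode constants at the working ionic
strength.

## What the simulator emulates

`simulation_scenario()` defines ground truth and `simulate_runs()`
generates run tables through the same physics the estimators invert:

* ionization at the apparent p$K_a$, itself temperature dependent through
  the dissociation enthalpy (default 7.4 kJ·mol$^{-1}$, a typical weakly
  endothermic hydroxycoumarin value) and through Van't Hoff scaling of the
  binding constants (default complexation enthalpy −20 kJ·mol$^{-1}$,
  i.e. exothermic, so complexation weakens on heating);
* fast-exchange population averaging of mobilities over
  free/complexed × protonated/deprotonated (single peaks, the standard
  affinity-CE assumption);
* viscosity-driven mobility growth of 2 % per °C applied to all species
  including the EOF marker;
* per-buffer currents varying 3 % per pH unit and 2 % per °C, feeding the
  two-section heating model self-consistently (single pass);
* migration times inverted per species including the ramp offset
  $t = L_{tot}L_{eff}/(U\mu_{app}) + 0.5\,t_{ramp}$;
* multiplicative Gaussian noise on *times* (CV 0.5 % by default, the
  repeatability class of a well-conditioned coated capillary), because
  times are the measured quantity;
* default design: six buffers (pH 3.0–8.0), triplicates, 25 °C, 30 kV,
  0.17 min ramp, 60/50 cm capillary with a 4 cm uncooled inlet.

The default binding constants (500 and 50 M$^{-1}$ at 10 mM host) give an
apparent shift of +0.60 pH units, the magnitude class of a strongly
shifting methylated β-cyclodextrin. The scenario uses the
counter-electroosmotic ordering (anion mobility −2.0×10$^{-8}$, EOF
+5.0×10$^{-8}$ m$^2$V$^{-1}$s$^{-1}$), under which the two correction
steps act in the opposite directions described above.

`scenario_dcs()` is the validation preset for the double correction
strategy: five coolant temperatures (15–55 °C) and *noise-free* times.
That choice is deliberate: the DCS targets systematic error, and the
per-temperature assertion "fully corrected is strictly closer to truth
than uncorrected" is a statement about systematics that random noise would
only blur. Noisy recovery is validated separately on the default scenario
(recovery within 0.05 pH units with CV 0.5 % and triplicates).

The simulator does **not** emulate: electropherogram traces (peak shapes,
baselines, electromigration dispersion), injection-plug or
pressure-assist effects, ionic-strength/activity effects on the
equilibria, slow-exchange peak splitting, or autothermal runaway. Passing
tests therefore demonstrate correctness of the estimation chain under the
stated observational model, not robustness to every instrumental artifact.
Spectra are simulated by mixing fixed acid/base form templates by the
ionization fraction; `template_spectra()` balances the base band so both
forms share the same total absorbance over the analysis pair, the condition
under which β is exactly affine in the ionization fraction.

## Numerical choices and degenerate inputs

* Sigmoid fits: Levenberg–Marquardt, 200 iterations max, deterministic
  restart offsets; non-convergence after five restarts is an error carrying
  the optimizer's message, never a silent fallback.
* `tvm_pka()` requires the mobility ratio strictly inside (0, 1) and
  reports "fully ionized or fully neutral" otherwise; equal signs of the
  two mobilities are required, so EOF sign conventions cannot silently
  flip a ratio.
* `vant_hoff()` accepts two temperatures with a warning (closed-form line,
  no residual error) and rejects a single duplicated temperature.
* Mobility–temperature models refuse fewer points than `degree + 1`;
  read-outs beyond the fitted temperature range are flagged, not refused,
  because mild extrapolation to the lowest temperature of interest is part
  of the published procedure.
* Run-table validation reports the offending row indices; a ramp time not
  smaller than both migration times is rejected at the boundary, since the
  corrected reciprocal time would diverge.
* Replicates are averaged (mean, sample SD) per (analyte, buffer, pH,
  temperature) cell before fitting; pooled per-replicate fitting is
  available via `mobility_summary(pool = TRUE)`.

## Validation problem sizes

The shipped test-suite and acceptance script work at desk scale: six-buffer
designs with triplicates (18 runs per system and temperature), five-point
temperature grids (90 runs per DCS system), 200-iterate Monte Carlo checks
of fit bias, and exhaustive inversion checks over a 17×17 (p$K_a$, pH)
grid. These sizes match the published protocol (5–6 buffers, triplicate
injections, five temperatures) rather than stress-testing asymptotics.

## Known limitations

* Apparent p$K_a$ values only; binding constants and complexation
  thermodynamics are not estimated.
* Monoprotic model; no zwitterions, overlapping p$K_a$ values, or charged
  hosts in the mobility route (the spectral route exists for those).
* The two-section heating model is linear in power per unit length;
  instruments with strongly nonlinear cooling response need their own
  calibration of the section coefficients, and higher-order SUMET behavior
  is outside the module's contract.
* The entropic term is reported both ways (see above); users comparing
  against published tables should check which convention those tables use.
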