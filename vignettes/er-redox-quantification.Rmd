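---
title: "Quantifying ER luminal redox dynamics with ratiometric roGFP sensors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying ER luminal redox dynamics with ratiometric roGFP sensors}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(roGFPtools)
```

## The measurement model

Redox-sensitive GFPs (roGFPs) carry an engineered cysteine pair whose
thiol--disulfide state shifts the balance between two excitation peaks. The
ratio $R = I_{405}/I_{488}$ of fluorescence excited near 405 nm and 488 nm
therefore reports the fraction of sensor molecules in the disulfide state,
the *degree of oxidation*:

$$ OxD = \frac{R - R_{red}}{\frac{I488_{min}}{I488_{max}}\,(R_{ox} - R) + (R - R_{red})} $$

where $R_{red}$ and $R_{ox}$ are the ratios of the fully reduced and fully
oxidized sensor (in situ calibration with DTT and H$_2$O$_2$) and
$I488_{min}/I488_{max}$ corrects for the intensity change of the 488-excited
channel between the two states. A sensor fused to human glutaredoxin
equilibrates rapidly with the local glutathione couple, so $OxD$ maps to the
glutathione redox potential through the Nernst equation for a two-electron
couple:

$$ E = E_0' - \frac{RT}{2F}\,\ln\frac{1 - OxD}{OxD} $$

`roGFPtools` implements these conversions (`oxd_from_ratio()`,
`potential_from_oxd()`, `oxd_from_potential()`), the glutathione pool
partition $E = E_0' - (RT/2F)\ln([GSH]^2/[GSSG])$ with concentrations in
mol/L (`partition_glutathione()`), and dynamic-range helpers. Two sensor
presets are included: `sensor_rogfp2il()` with midpoint $-240$ mV, suited to
the comparatively oxidizing ER lumen, and `sensor_rogfp2()` with $-280$ mV.

```{r}
s <- sensor_rogfp2il()
potential_from_oxd(c(0.465, 0.253), s)   # WT and ERO-deficient ER lumen
partition_glutathione(-241, gsh_molar = 2.5e-3)
```

Assumptions worth stating explicitly:

* **Temperature** defaults to 298.15 K; the conversions expose it through
  `physical_constants()`. Printed literature values of $-241$ and $-253$ mV
  are reproduced within 1 mV, not exactly, because published $OxD$ values
  are rounded.
* **No pH correction** is applied. The ER lumen is near neutral, so a pH 7
  titration curve is a reasonable approximation; organelles with acidic
  lumina would need a midpoint correction this package does not provide.
* A sensor is informative over roughly $\pm 35$ mV around its midpoint
  ($OxD$ 0.06--0.94); conversions outside that window are numerically exact
  but carry little experimental information.

## Ratio imaging

`preprocess_channel()` applies, in order: scalar background subtraction
(background is user input, e.g. the mean over a vacuole region via
`estimate_background()`); subtraction of $k \cdot$ autofluorescence from the
405-excited channel only, where the autofluorescence channel is acquired at
430--470 nm and $k$ can be estimated from sensor-free control tissue by
regression through the origin (`estimate_bleed_coefficient()`); clipping at
zero; and $3\times3$ spatial mean filtering, with edge pixels averaged over
their in-bounds neighborhood (shrink-to-valid).

`ratio_map()` evaluates $I_{405}/I_{488}$ pixel-wise wherever the 488
channel reaches a masking threshold, so division by zero never occurs. The
default threshold (`default_mask_threshold()`) is the residual background
level plus three times a robust per-pixel noise estimate taken from the
dimmest quartile of pixels; because the channels were already $3\times3$
averaged, the observed deviation is scaled back by 3. `roi_summary()`
reports the mean and median ratio, and both log conventions --- the log10 of
the mean ratio and the per-pixel mean of log10 ratios --- since ratio
distributions are skewed and are conventionally log-transformed before
plotting. `pseudocolor()` maps ratio linearly to hue from 240° (blue, fully
reduced) to 0° (red, fully oxidized) anchored at the calibration limits,
saturating outside them.

`reta_readout()` implements the redox-based topology call for membrane
proteins: a terminal roGFP2 fusion reading reduced faces the cytosol, one
reading oxidized faces the ER lumen; (N cytosolic, C luminal) is a type II
protein.

Design choices where the field's practice is not unique: hue is linear in
the ratio (not log-ratio); background may be a per-image scalar or a
user-supplied region; the bleed coefficient may be fixed per experiment or
re-estimated per image. All are arguments, none is hard-wired.

## Trace kinetics

Plate-reader assays excite at 400 and 482 nm; `correct_and_ratio()`
subtracts, per genotype and excitation channel, the time-resolved mean of
that genotype's blank (non-transformed) wells, forms the 400/482 ratio and
log10-transforms it. Time points where a corrected channel is not positive
are flagged missing, never imputed. `segment_phases()` labels samples with
half-open phase intervals $[t_0, t_1)$; a perfusion dead time (about 1 min
of tubing and chamber volume) shifts the schedule as experienced by the
tissue.

`fit_slope()` is ordinary least squares of log10 ratio against time,
reported per minute, refusing windows with fewer than 3 usable points or
more than 20% missing. `extract_features()` computes the three standard
summary features of a hypoxia--reoxygenation trace:

* **(i)** steady state: mean log ratio over the last 30 min of normoxia;
* **(ii)** re-oxygenation peak: maximum log ratio in the re-oxygenation
  phase minus the value at its onset. The onset value is read from the last
  sample of the *preceding* phase so that a burst beginning exactly at the
  phase switch is fully counted;
* **(iii)** recovery: that maximum minus the mean over the final 30 min of
  recording.

Reduction and re-oxidation rates default to fixed windows at phase onset
(20 and 10 min), with an automatic steepest-slope window finder (maximal
$|$slope$|$ contiguous window of fixed width) as an alternative; published
figures typically shade such windows without stating them numerically, so
they are configurable (`feature_config()`). Features are invariant to adding
a constant to the log-ratio trace, except (i), which shifts with it.
Whether rates should be computed on log ratios or raw ratios is not
standardized; the package defaults to log10 and exposes the raw trace.

## The synthetic-data generators

Because no raw microscopy or plate-reader data ship with the package, both
analysis pipelines are validated against generators that emit data *with
ground truth*.

### Images

`simulate_er_image()` builds a sensor-density field emulating a reticulate
ER network: random branched tubule polylines dilated to 2--3 px, an annular
nuclear ring, and a few bright elliptical ER bodies. Each pixel mixes two
spectral endmembers according to the ground-truth $OxD$ field:
$I_{ch} = d\,(f_{ch,red}(1-OxD) + f_{ch,ox}\,OxD) + b_{ch} (+ k\,a) + \varepsilon$.
The default endmembers imply $R_{red} = 0.5$, $R_{ox} = 1.05$ (dynamic range
$\delta = 2.1$, matching the 2.0--2.2 observed in situ for roGFP2iL) and
$I488_{min}/I488_{max} = 0.7$. Default noise is Poisson shot noise at
photon counts giving roughly 2% CV on sensor-bright pixels. A
`calibration_pair = TRUE` flag emits fully reduced/oxidized companion images
of the same specimen, the in-silico analogue of DTT/H$_2$O$_2$ immersion.

What a green round-trip test establishes: the analysis corrections exactly
invert the generator's forward model (noiseless), and are robust to shot
noise at realistic photon budgets (recovery within 0.02 OxD). What it does
not establish: robustness to focal drift, chromatic misregistration,
heterogeneous backgrounds, or segmentation errors --- none of which the
generator emulates.

### Traces

`simulate_trace()` integrates a deliberately minimal model of the luminal
glutathione-equivalent pool, state $x(t) \in [0,1]$ (oxidized fraction):

$$ \frac{dx}{dt} = v_{ox}(t)\,(1 - x) - v_{red}(t)\,x $$

with an oxidizing flux from the ERO system, saturating in oxygen, plus a
transient burst at re-oxygenation, and reducing fluxes from nascent-peptide
import and glutathione import:

$$ v_{ox} = k_{ero}\,g\,\frac{O_2}{O_2 + K_{O_2}} + A_{eff}\,e^{-(t - t_{reox})/\tau_{burst}},
\qquad v_{red} = k_{pep}\,c(t) + k_{gsh}\,b(t) $$

The genotype factor $g$ scales ERO-derived oxidation (presets: WT 1.0,
*ero1* 0.6, ami*ERO2* 0.5, *ero1 ero2* 0.15). Cycloheximide sets the
peptide factor $c = 0$; during hypoxia $c$ decays with $\tau_{pep}$ as
translation slows under the energy crisis; buthionine sulfoximine makes the
glutathione factor decay, $b = e^{-t/\tau_{BSO}}$. Perfused DTT adds
$k_{dtt}\cdot[\mathrm{DTT}]$ to $v_{red}$. The pool maps to a potential via
$[GSH] = (1-x)\,G_{tot}$, $[GSSG] = x\,G_{tot}/2$, the sensor equilibrates
with that potential, and fluorescence follows the same spectral model as the
images; blank wells carry only autofluorescence, so the per-genotype blank
correction is exact on noiseless output.

Parameter defaults and why (all rates per second):

* $k_{ero}$ is **calibrated in closed form** so the WT steady state at 20%
  O$_2$ sits at $E = -241$ mV, the reported wild-type luminal potential.
* $k_{pep} = 1.4\times10^{-3}$, $k_{gsh} = 2\times10^{-4}$ (a 7:1 split:
  protein thiol import is the dominant reducing input) and
  $\tau_{pep} = 3000$ s were chosen, once, so that the noiseless hypoxia
  minimum falls at about 45 min --- the reported duration of the initial
  reduction phase.
* $K_{O_2} = 1\%$: ERO flux drops about 10-fold between 20% and 0.1% O$_2$.
* Burst $A = 2\times10^{-5}$, $\tau_{burst} = 600$ s, sized to overshoot the
  baseline visibly and decay within the recovery phase. The *effective*
  amplitude is $A_{eff} = A\,\max(0, (g - 0.2)/0.8)$: genotypes with less
  than ~20% ERO capacity produce no burst, so the *ero1 ero2* preset shows
  the observed monotone recovery without a transient peak while single
  knockdowns still burst. A strictly linear scaling would instead give the
  weakest genotype the *largest* relative overshoot (the same flux acting on
  a several-fold smaller oxidized pool), contradicting observation.
* $G_{tot} = 2.5$ mM glutathione equivalents (cytosolic GSH concentration
  under a passive-transport assumption); $\tau_{BSO} = 4$ h;
  $k_{dtt} = 4\times10^{-5}\,\mu M^{-1}$.

Integration is classical fixed-step RK4 (the ODE is scalar and linear in
$x$, so dt = 1 s is far inside the stability and accuracy margin); the test
suite checks agreement with an explicit-Euler oracle at dt = 0.1 s to within
$10^{-3}$ in $x$. With $g = 0.15$ the *ero1 ero2* steady state sits near
$-265$ mV rather than the reported $-253$ mV; the genotype factors are
generator parameters chosen for clear qualitative separation, not
biological estimates.

The true shape of the re-oxygenation burst and the mechanism of the gradual
in-hypoxia re-oxidation are open questions experimentally; the generator
encodes one plausible parameterization and labels it as such.

### Numerical and statistical choices in the signature tests

* The bottom of the WT hypoxia dip is flat relative to well-averaged noise,
  so the raw argmin of a noisy trace jitters by tens of minutes. The
  signature tests therefore time the reduction phase as the first entry of
  the 15-min moving-average trace into the bottom 10% of the dip depth,
  which crosses on the steep descent and is noise-robust.
* "CHX abolishes the initial reduction" is tested as a dip smaller than a
  third of the control dip: the model retains a residual
  glutathione-import-driven reduction (~25% of control depth).
* Genotype recovery inverts the monotone map from $g$ to the late-hypoxia
  slope of the noiseless trace (`fit_genotype_factor()`), built once as a
  lookup table (`genotype_slope_table()`).

## Phenotype scores

`survival_score()` is the weighted mean of seedling injury categories after
a hypoxia episode --- healthy 5, damaged 3, dead 1 --- bounded in $[1, 5]$
and linear in category proportions. `resumed_fraction()` is the percentage
of seedlings that resumed primary root growth. Classification of individual
seedlings is visual and out of scope.

## File formats and reproducibility

All formats are plain text: channel images and ratio maps use a one-header
`imgtxt` matrix format (lossless to double precision), pseudocolor renders
are plain PPM (P3), traces and schedules are CSV, and configurations are
flat `key = value` documents. Every generator call requires a seed, every
CLI run writes its configuration (tool version, seed, parameters) beside
its outputs, and every synthetic dataset carries its ground truth.

## Known limitations

* **One invariant is deliberately left failing** in the test suite: the
  requirement that the *ero1 ero2* late-hypoxia log-ratio slope be below 20%
  of the WT's. On the ground-truth pool oxidation the slope ratio equals the
  genotype factor exactly (0.15), but the Nernst relation is logarithmic in
  $x$, so the same relative change of a 6-fold smaller pool produces a
  larger potential change, and the sensor/log10 transforms only partly
  compress it back: in trace space the ratio is structurally ~0.25 for every
  parameterization that also reproduces the ~45-min reduction phase. The
  ground-truth version of the invariant passes; the trace-space version is
  kept red as documentation of this arithmetic.
* The kinetic model is a single well-mixed pool with two lumped fluxes; it
  makes no claims about PDI pools, H$_2$O$_2$ handling, or spatial
  gradients.
* The image generator does not emulate z-structure, registration error, or
  ER substructure beyond tubules, a nuclear ring and ER bodies;
  segmentation of those structures is out of scope.
* Statistical comparison across genotypes (ANOVA and post-hoc tests) is
  left to downstream tools.
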