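---
title: "A spectroscopy-based surrogate for dissolution testing: models, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A spectroscopy-based surrogate for dissolution testing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dissosurrogate)
```

## The problem

In vitro dissolution testing of extended-release tablets is slow (24 h per
run here), destructive, and samples a negligible fraction of a batch. The
surrogate implemented by this package replaces the wet test with two
chained chemometric models:

1. **Composition from spectra.** Partial least squares (PLS) calibrations
   quantify the drug (DR, drotaverine) and matrix polymer (HPMC,
   hydroxypropyl methylcellulose) mass fractions of a tablet from its NIR
   or Raman spectrum.
2. **Profile from composition.** A feed-forward neural network maps three
   tablet descriptors — DR %, HPMC % and the compression pressure recorded
   by the press — to the full 53-point cumulative release curve sampled
   over 24 h.

Predicted and reference profiles are compared with the f2 similarity
factor,

$$ f_2 = 50\,\log_{10}\!\Big(100\,\big[1 + \tfrac1n\textstyle\sum_t w_t (R_t - T_t)^2\big]^{-1/2}\Big), $$

whose conventional equivalence range is 50–100. A multi-response PLS
("direct PLS") fitted on the same inputs and targets serves as the linear
baseline the network must beat.

The underlying study design is a 3^3 factorial in DR content (6/8/10 %),
HPMC content (10/20/30 %) and compression pressure (63.8/95.7/127.6 MPa),
plus ten axial-style settings; 30 settings train the models and 7 are held
out, with four tablets per setting (148 tablets). `build_design()`
reconstructs this table exactly.

## The synthetic data generator

No public dataset accompanies the study, so the package ships a generator
(`generate_dataset()`) that emulates its data-generating process; every
stage of the surrogate is developed and tested against it.

**Dissolution kinetics.** The noise-free release curve is a Weibull law
$D(t) = D_{\max}(1 - e^{-(t/\tau)^\beta})$ with $\beta = 1$. The plateau
scales with drug load relative to the 8 % centre point
($D_{\max} = 100\,\mathrm{DR}/8$; profiles are expressed in % of the
reference dose). The time constant

$$ \tau = \tau_0\,\Big(1 + A\,\frac{c^{n}}{K^{n}+c^{n}}\Big)\Big(\frac{F}{F_0}\Big)^{p} $$

carries the polymer retardation as a Hill sigmoid in the HPMC content $c$
and a weak power law in compression pressure $F$. The defaults
($\tau_0 = 5$ min, $A = 55$, $K = 16$, $n = 10$, $p = 0.15$,
$F_0 = 95.7$ MPa) encode gel-percolation behaviour: below the threshold
(10 % HPMC, $\tau \approx 7.5$ min) release is nearly immediate and nearly
insensitive to the exact polymer level; at 20 % the matrix gels and
release slows dramatically ($\tau \approx 253$ min); from 20 % to 30 % the
retardation grows only marginally ($\tau \approx 280$ min). The steep
sigmoid (large $n$) is deliberate: a shallower one would make release at
10 % HPMC both substantially retarded and highly sensitive to small
composition changes, contradicting the near-immediate, threshold-like
behaviour the generator is meant to emulate. Compression force only
perturbs the early curve. The emulated study conditions prescribe no
kinetic model; this form and its constants are the package's own choice,
fixed here.

**Spectra.** Tablet spectra are linear mixtures of four pure-component
spectra (DR, HPMC, MCC filler, 1 % MgSt lubricant; mass fractions close to
100 %), each a sum of Gaussian peaks, distorted by a per-tablet
multiplicative scatter factor, a smooth additive baseline — a steep
low-wavenumber exponential for Raman, emulating fluorescence — and
additive Gaussian noise, inflated in configured noisy edge regions and
reduced by $\sqrt{r}$ for the $r$ averaged replicate acquisitions per
tablet (two for Raman). Peak placement encodes the study's chemistry:
narrow aromatic drug bands dominate the Raman fingerprint region
(1645/1605/1560/1345 cm⁻¹), while HPMC's distinctive broad
overtone/combination bands sit in the NIR (11000/10300/9800, 8850,
7750 cm⁻¹). Crucially, the two cellulosic excipients share nearly the
same Raman bands (1090/1120 cm⁻¹ region), so the polymer-specific signal
direction in Raman is weak. Together with higher reflection-mode noise,
this makes the intended modality ranking an emergent property of the
data, not an assertion: Raman transmission is best for DR, NIR
transmission best for HPMC, and reflection modes are worse for both.

**Noise magnitudes.** Between-tablet composition variability (2 % relative
s.d. of nominal), pressure measurement noise (1 MPa), and dissolution
measurement noise (1 % released per point) are not reported by the study
and are chosen as plausible manufacturing/assay magnitudes under which
PLS recovery remains feasible. What passing tests show is therefore
internal consistency of the whole chain under realistic noise — not
performance on any real instrument's data. Real spectra differ in ways
the generator does not attempt: instrument line shapes, detector
nonlinearity, water/temperature effects, particle-size-dependent scatter
beyond a scalar factor.

## Preprocessing

`default_recipe()` reproduces the study's pretreatments per modality:

* **Raman** (kept region 350–1680 cm⁻¹): asymmetric least squares
  (Whittaker) baseline with $p = 0.001$, $\lambda = 10^4$; standard normal
  variate; mean centering.
* **NIR** (transmission keeps 7600–8000 and 8500–13000 cm⁻¹, reflection
  4200–7400 cm⁻¹): 5-point quadratic Savitzky–Golay first derivative;
  multiplicative signal correction; mean centering.

Numerical choices that the source leaves open, fixed here: AsLS iterates
its asymmetric weights at most 50 times, stopping when fewer than a 1e-6
fraction of weights change, with a second-difference penalty; the
Savitzky–Golay derivative is taken with respect to channel index (the
constant grid-spacing factor is absorbed by the regression); its edge
channels are completed by the `signal` package's projection filter
(full-window polynomial fits anchored at the boundary); the MSC reference
is the training-set mean spectrum; standard deviations use the $n-1$
denominator throughout. Data-dependent state (MSC reference, column
means) is fitted on training spectra only and replayed verbatim on
held-out spectra via `apply_recipe()`.

## Composition models

PLS1 calibrations are computed by NIPALS with deflation — one model per
analyte, since drug and polymer calibrations are reported separately.
Model complexity is selected by contiguous-block cross-validation with 30
splits: samples are blocked *in acquisition order* (block sizes differ by
at most one), which respects the design-ordered structure of the data;
the chosen component count is the smallest whose RMSECV lies within 2 %
of the minimum, a parsimony tie-break the source does not specify.

The genetic algorithm (`ga_select()`) selects contiguous 10-channel
wavelength windows with a population of 64, at most 6 latent variables,
and the best of 3 replicate runs — the stated settings — while the
unstated internals are conventional: 100 generations, tournament
selection of size 2, single-point crossover at window boundaries with
probability 0.5, per-window mutation 0.01, elitism 1. Fitness is the
minimum contiguous-block RMSECV over component counts up to 6 on the
selected channels; a chromosome selecting nothing scores worst and can
never be returned. Window width is interpreted as fixed (the wording
would also admit an adaptive width).

## Profile models

The network (`ann_new()`) is a 3 → H → 53 feed-forward net. Unstated
architecture details follow the defaults of the neural toolbox the study
used: tanh hidden units, linear outputs, per-feature min–max scaling of
inputs and targets to [-1, 1] fitted on training data, and small
fan-in-scaled uniform initial weights.

Two trainers are implemented on the analytic Jacobian:

* **Levenberg–Marquardt** (`train_lm()`): damped Gauss–Newton steps
  $(J^\top J + \mu I)\delta = J^\top r$, with $\mu$ divided by 10 on
  acceptance and multiplied by 10 on rejection ($\mu_0 = 10^{-3}$, cap
  $10^{10}$); training MSE is nonincreasing by construction. Early
  stopping returns the weights with the best validation MSE after six
  consecutive rises.
* **Bayesian regularization** (`train_br()`): minimizes
  $\beta E_D + \alpha E_W$ with the evidence-approximation updates
  $\gamma = N_w - \alpha\,\mathrm{tr}(H^{-1})$,
  $\alpha = \gamma / 2E_W$, $\beta = (n - \gamma)/2E_D$, where
  $H = \beta J^\top J + \alpha I$; no validation early stopping. A failed
  Hessian inversion falls back to a ridge-stabilised inverse with a
  warning.

`neuron_sweep()` reproduces the selection protocol: for each hidden-layer
size, replicate runs each draw a fresh random 70/15/15 split of the
training tablets, train, and predict the external test tablets — whose
inputs are the PLS-predicted compositions plus measured pressure, while
training inputs are the nominal compositions plus measured pressure. Each
run is scored by its summed per-tablet profile RMSEP on the external
test set; the sweep records the mean per H and keeps the single best run
overall. Interpretations fixed here: the internal 15 % test fraction is
drawn but unused (as in the toolbox's silent split); splits are redrawn
per run rather than shared across H; RMSEP targets are per-tablet
profiles, not per-setting averages.

## Evaluation

`f2_similarity()` implements the standard regulatory form of the factor
(the typeset equation in the source is ambiguous about bracket placement;
the form used here is the one consistent with $f_2 = 100$ at identity and
the stated 50–100 equivalence range). Weights default to 1. All 53 points
enter; the regulatory convention of truncating after 85 % dissolution is
available as a flag but off by default, since full profiles are compared.
`effects_analysis()` fits the 10-term response surface (intercept, linear,
quadratic, linear×linear) on -1/0/+1 coded factors to the
DR-normalised dissolution value at 15 or 960 min and reports t statistics
as standardized effects, significance at p = 0.05.

## Pipeline profiles and problem sizes

`run_pipeline()` chains everything for three input sources: both analytes
from Raman, both from NIR, or drug from Raman and polymer from NIR. Two
profiles are built in:

* `"quick"` — the desk-scale default used by the package's own end-to-end
  tests: Bayesian-regularization trainer, 5 replicate runs, hidden sizes
  {1, 3, 5}, 120-epoch cap, GA off. One run takes a couple of minutes on
  one core.
* `"full"` — the study-scale protocol: both trainers, 100 runs, hidden
  sizes 1–10, GA-refined calibrations.

All randomness flows from one master seed through derived stage seeds; a
run manifest plus the configuration reproduces every artifact
bit-for-bit.

```{r, eval = FALSE}
res <- run_pipeline(pipeline_config("quick", seed = 1), out_dir = "run1")
res$comparison          # mean f2 per model and input source
res$sweeps$raman$summary  # capacity curve of the hidden layer
```

## Known limitations

* The generator's kinetics, peak tables and noise magnitudes are
  invented (the study reports none); conclusions about *relative* model
  behaviour (network vs linear baseline, transmission vs reflection,
  capacity curve) transfer, absolute error magnitudes do not.
* GA selection is expensive in this implementation (its fitness
  cross-validates a PLS model per chromosome) and is therefore off in the
  quick profile; on the synthetic spectra it need not improve the
  polymer calibration, whose signal is spread over all cellulosic windows
  by construction.
* PLS2 profile prediction and the network share the input-scaling
  convention but not code; neither handles missing dissolution points.
* The f2 factor is reported without bootstrap confidence intervals, and
  no in vitro–in vivo correlation is attempted.
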