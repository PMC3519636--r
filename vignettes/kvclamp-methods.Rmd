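---
title: "Gating models, protocols and fitting methods in kvclamp"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Gating models, protocols and fitting methods in kvclamp}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kvclamp)
```

## What this package does

kvclamp characterizes voltage-gated Shaker-family K⁺ channels the way an
electrophysiologist does at the rig, but against a synthetic oocyte: a
parametric gating model is integrated through the standard voltage-clamp
protocols (100-ms step families, 5-s steady-state-inactivation pre-pulses,
isochronal tail protocols in symmetrical K⁺, deactivation tails, 400-ms
whole-cell co-expression families), recording artifacts are added and removed
again by P/N subtraction, and the resulting sweeps are pushed through
Boltzmann and exponential fitting pipelines to produce a summary-table row
per channel: inactivation time constant(s) at +60 mV, steady-state
inactivation (SSI) midpoint and slope, conductance–voltage (GV) midpoint and
slope, and phenotype labels. A registry of six sea-anemone Shaker channel
parameter sets (NvShak1–6) and eleven regulatory-subunit heteromer presets
drives the end-to-end checks; `reproduce_table1()` runs the whole loop and
compares recovered to configured values.

## The gating model

The model is a phenomenological Hodgkin–Huxley decomposition. Ionic current
is

$$I(t) = g_{\max}\, P_o(t)\, h(t)\, (V - E_K),$$

with $E_K$ the Nernst potential of the configured solutions. Activation and
inactivation are separable; this is the same assumption the fitting
procedures make, which is what lets noiseless simulations recover configured
parameters exactly.

**Activation.** Steady-state open probability is a Boltzmann function
$P_\infty(V) = 1/(1+e^{-(V-V_{50})/s})$. Three modes map it onto kinetics:

* `macroscopic` (default, used by every recovery check): $P_o$ relaxes
  mono-exponentially toward $P_\infty(V)$ with $\tau_{act}(V)$ on
  depolarization and $\tau_{deact}(V)$ on repolarization. Because the
  relaxation is exponential within each constant-voltage epoch, sweeps are
  evaluated in closed form — there is no ODE solver and no integration
  error.
* `mechanistic`: $P_o = m^{n}$ with $n$ independent two-state gates; the
  per-gate midpoint is shifted by $s\,\ln(2^{1/n}-1)$ so $P_\infty$ still
  crosses 0.5 at the configured $V_{50}$. This mode produces the sigmoidal
  activation delay caused by traversing multiple closed states, which the
  delay statistic quantifies. With $n=1$ it is identical to macroscopic
  mode (a property the tests assert).
* `instantaneous_activation`: $P_o \equiv P_\infty(V)$. Used to isolate
  inactivation decays, whose time constants are then recovered exactly.

The kinetic closure from reported time constants to forward/backward rates
(`kinetic_rates()`) uses $\alpha + \beta = 1/\tau$, $m_\infty = \alpha\tau$.

**Time-constant voltage dependence.** $\tau_{act}(V)$ shrinks e-fold per
`tau_act_vslope` (default 80 mV) referenced to +60 mV; $\tau_{deact}(V)$
grows e-fold per `tau_deact_vslope` (default 40 mV) referenced to −100 mV,
making $\log\tau_{deact}$ linear in voltage — the semi-logarithmic relation
the deactivation analysis plots. Activation/deactivation time constants are
not published numerically for these channels, only as rank orders; the
registry encodes the ranks (activation: NvShak5 fastest 0.7 ms … NvShak1
slowest 3.5 ms at +60 mV; deactivation: NvShak6 fastest 1.2 ms … NvShak1
slowest 12 ms at −100 mV, a 10-fold span) and these values are flagged
illustrative, not acceptance-grade.

**Inactivation.** Each channel carries a list of inactivation components
with mechanism `N_type` (ball-and-chain, removed by N-terminal truncation),
`C_type` (pore collapse, suppressed by high external K⁺) or `intrinsic`
(removed by neither). Component $j$ contributes fractional amplitude $f_j$
to the availability $h(t) = \mathrm{ped} + \sum_j f_j h_j(t)$, with pedestal
$1-\sum_j f_j$; each $h_j$ relaxes first-order toward its own Boltzmann
$h_{\infty,j}(V)$. Development kinetics (`tau_inact`, treated as
voltage-independent) apply at and above 0 mV; below 0 mV availability
follows `tau_recovery`. C-type rates scale with external K⁺ as
$k_{1/2}/(k_{1/2}+[K^+]_o)$, normalized so the configured `tau_inact` is
realized at the standard 2 mM recording condition — the condition under
which the published time constants were measured. At 140 mM the C-type rate
falls to ~5 % of its reference value, which is why symmetrical-K⁺ tail
protocols effectively silence C-type inactivation.

**NvShak6.** Its partial inactivation is removed by neither truncation nor
K⁺, so the fixture models it as a single `intrinsic` component with
fraction 0.6 (pedestal 0.4). The unpublished kinetics are set to
`tau_inact = tau_recovery = 150` ms. Equal development and recovery time
constants make the availability relaxation smooth across 0 mV; with a
kinetic discontinuity there, the 100-ms-step GV of this non-truncatable
channel would be non-monotonic around threshold and the Boltzmann fit would
not return the configured parameters.

**Heteromers.** A co-expression experiment is a `heteromer_mix`: recorded
current is $(1-f)\,I_{hom} + f\,I_{het}$. The whole-cell homomeric
reference uses a depolarized activation midpoint (+18 mV) so that its first
detectable current step is +10 mV, matching the whole-cell controls, which
activate at more depolarized potentials than excised patches. All numeric
heteromer preset parameters encode qualitative published phenotype levels
and are illustrative.

## Protocols and the simulator

Protocols are ordered constant-voltage epochs; one epoch may vary across
sweeps on an arithmetic grid. Defaults follow the published designs: the
step family is 100-ms steps from −60 to +60 mV in 10-mV increments from a
−100 mV hold (13 sweeps); SSI uses 5-s pre-pulses from −120 to 0 mV with a
+60 mV test pulse; deactivation tails run at −160 … −80 mV after a +50 mV
pulse; the co-expression family is 400-ms steps from −20 to +20 mV.

One deliberate addition: the SSI preset inserts a 50-ms deactivating
interpulse at −120 mV between pre-pulse and test pulse (`gap_duration = 0`
removes it). Without it, channels opened by depolarized pre-pulses enter
the test pulse already conducting, and the peak test current confounds
availability with carried-over open probability. The bias is invisible when
activation and inactivation ranges are well separated but shifts the fitted
SSI midpoint by several millivolts for a channel like NvShak1 whose two
midpoints nearly coincide (−20.3 vs −19.5 mV). Availability recovered
during the interpulse is affine in the conditioned availability, so it is
absorbed exactly by the free pedestal of the decreasing Boltzmann fit and
leaves the recovered midpoint and slope unbiased; the test suite verifies
recovery to within 0.01 mV for all four inactivating channels.

Artifacts are linear leak $g_{leak}(V-E_{leak})$ (presets stay under the
~50 nA scale of a well-clamped oocyte), capacitive spikes at epoch
boundaries (amplitude $c_m\,\Delta V/\tau_{cap}$, $\tau_{cap}=0.1$ ms) and
additive Gaussian noise drawn from a locally seeded generator — identical
seeds give bit-identical recordings, and the simulator restores the
caller's RNG state.

**P/N subtraction** (`pn_leak_subtract()`) regenerates `n_sub` sub-sweeps
whose deviations from a hyperpolarized sub-holding potential are the main
deviations scaled by $-1/n$ (P/−4 by default), so channels never open in
the sub-pulses. Any strictly linear component — leak and capacitive spikes —
cancels exactly by construction; a pooled linearity check on the sub-sweep
steady currents warns when the sub-pulse range activates channels. The
residual after subtraction is the genuine sub-threshold channel current at
the sub-holding potential, bounded in the tests by
$10^{-6} g_{\max}|V-E_K|$.

## Fitting procedures

All nonlinear fits run Levenberg–Marquardt (`minpack.lm::nls.lm`) on
residual functions with box constraints; working on residuals directly
(rather than through a model-frame interface) keeps the fits stable when
noiseless synthetic data are reproduced to machine precision. Initial
guesses follow rig conventions: the Boltzmann midpoint starts at the
half-range crossing with a 5-mV slope; exponential time constants start at
the time to reach $1-1/e$ of the span.

* `fit_boltzmann()` fits $g(V) = (A_1-A_2)/(1+e^{(V-V_{50})/s}) + A_2$;
  normalized variants fix the asymptotes (0→1 for activation, 1→free
  pedestal for availability). Direction is inferred from the data; slope is
  kept positive. Fewer than 4 points is an error; fewer than 5 sets a
  low-confidence flag.
* `fit_exponential()` fits $I(t) = I_i + A e^{-t/\tau}$ to decays and
  rises; flat traces raise a degenerate-fit error.
* `fit_double_exponential()` peels a slow component off the tail
  two-thirds, fits both components jointly, orders them fast-first and
  reports fractional amplitudes $f_j = |A_j|/(|A_1|+|A_2|)$.
* `select_inactivation_model()` prefers the single exponential unless a
  nested F-test rejects it at α = 0.01 **and** the time constants are
  separated more than 3-fold **and** the minor component carries at least
  5 % of the amplitude. The amplitude guard exists because on noiseless
  data the F statistic diverges for arbitrarily small true second
  components; ties prefer the simpler model.
* `activation_delay_and_tau()` fits the late phase of activation (samples
  at ≥50 % of the final rise) with a single exponential and reports the
  delay as the time from pulse start to the fitted curve's zero-current
  intercept, $t_{zero} = t_{50} - \tau\ln(-I_{ss}/B)$. A mono-exponential
  rise from zero has zero delay by construction; a fitted curve that never
  crosses zero raises an undefined-delay error.
* `tail_amplitude()` fits the tail decay after a 0.3-ms settling blank and
  back-extrapolates to the instant of repolarization, a measurement robust
  to blanked capacitive samples and the operational meaning of
  "isochronal" used throughout.

**Curves.** `build_gv_curve()` converts per-sweep tail amplitudes to
conductances via the tail driving force, normalizes per cell, fits the
normalized Boltzmann per cell and reports the mean of per-cell fits
(mean ± SEM across cells for display; SEM is absent for a single cell).
`build_ssi_curve()` uses the peak absolute test-pulse current after a
0.3-ms blank, normalized per cell, with the decreasing Boltzmann.
`deactivation_tau_curve()` returns per-voltage tail time constants plus the
R² of the semi-log linear fit. `prepulse_difference()` subtracts the
depolarized-pre-pulse sweep from the hyperpolarized one; the hyperpolarized
sweep is zeroed on its pre-pulse-end baseline (true zero — channels closed),
while the depolarized sweep is aligned on the late-test steady level where
the two traces superimpose, so the difference vanishes identically when no
heteromeric channels are present. The difference's inactivating component
is its positive part; the early negative excursion is the activation-history
mismatch of the non-inactivating background and is ignored by the
phenotype classifier.

**Phenotype flags.** Threshold class is high iff GV $V_{50} \ge 0$ mV (the
boundary is closed on the high side to make the rule total). Heteromer
flags use calibration cutoffs stored in `heteromer_cutoffs()` rather than
hard-coded, because the published separations are qualitative: difference
trace τ < 15 ms very fast, < 60 ms fast, otherwise slow; first-appearance
shifts of 10/20/≥30 mV on the 10-mV protocol grid are small/medium/large
("first appearance" = most hyperpolarized step whose steady current exceeds
1 % of the top step); activation/deactivation τ ratios > 1.5 slow, < 0.67
fast. The activation rate is reported undetermined when fast heteromeric
inactivation obscures the rise, and any property whose recordings are
missing is undetermined rather than guessed.

## The PDZ motif scanner

`pdz_scan()` classifies protein C-terminal 4-mers against the Class I
PDZ-binding consensus. The default consensus is −3 ∈ {E, D}, −2 ∈ {S, T},
−1 any, 0 ∈ {V, L, I}; a near-consensus call requires exactly one
constrained position to deviate via the allowed-substitution table
(−3: H, Q; −2: F, G; 0: F). The table is reverse-engineered from the
observed near-consensus Shaker termini, not from a general conservation
rule, and both consensus and table are arguments. Accepting D at −3 is the
default's reading of the ambiguous case ending -DGFV, where the text does
not identify which residue is the single conservative substitution; a
stricter consensus (−3 = E only) is a one-argument override and then calls
that terminus `none`.

## Numerical choices and problem sizes

* Sampling: 0.05 ms for ≤400-ms epochs, 0.1 ms for long-pre-pulse
  protocols; the simulator warns when `dt` exceeds a fifth of the fastest
  configured time constant. Because epochs are evaluated in closed form,
  `dt` affects only where the solution is sampled, not its accuracy.
* Recovery checks simulate one noiseless cell per fixture (identical cells
  add no information at zero noise); the multi-cell path (mean ± SEM,
  per-cell fits) is exercised with 5 identical cells in the tests. The
  full six-channel loop runs in about two seconds.
* The Monte-Carlo bias check adds Gaussian noise (σ = 0.02 of the
  normalized amplitude) to a 13-point GV curve over 200 replicates under a
  fixed seed and requires mean midpoint bias below 0.3 mV.
* Tolerances asserted end-to-end: 0.5 mV on midpoints, 0.2 mV on slopes,
  2 % on inactivation time constants.

## What the synthetic data do and do not show

The simulator reproduces the separable-gating world the analysis assumes.
Passing recovery tests therefore demonstrates that the pipeline is
self-consistent and unbiased under the model, at the printed parameter
values, with realistic protocols and artifacts — not that the model is an
adequate description of any particular recording. Real oocyte data add
series-resistance and space-clamp errors, channel rundown, endogenous
currents, correlated noise and cell-to-cell parameter spread, none of which
are modelled; there is no single-channel stochasticity, no temperature
dependence, and K⁺ is the only permeant ion. Two consequences worth
noting: the truncated NvShak4 construct retains ~3 % C-type relaxation
over a 100-ms step even in 140 mM K⁺, so its recovered GV slope sits
0.15 mV above the configured value (within tolerance — suppression, not
elimination, is the modelled behavior); and heteromer flags are only as
meaningful as the preset parameters, which encode qualitative published
levels.

## Known limitations

* Inactivation development kinetics are voltage-independent above 0 mV;
  channels whose τ varies strongly with voltage in that range are outside
  the model.
* The double-exponential fitter is intended for well-separated components;
  with τ ratios below ~2 the amplitudes are poorly identified (the model
  selector's separation guard exists for this reason).
* `compare_heteromer()` assumes the homomeric background does not
  inactivate, as in the co-expression assay it models.
* The episodic-sweep text format stores values at 9 significant digits;
  round-tripping is bit-stable at that precision, not at full binary
  precision.
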