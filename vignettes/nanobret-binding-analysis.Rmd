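---
title: "Models and methods for live-cell NanoBRET binding analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods for live-cell NanoBRET binding analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bretfit)
```

## The assay and its signal

NanoBRET ligand-binding assays read out the proximity between a luciferase
(NanoLuc) fused to a receptor's extracellular N terminus and a fluorophore
conjugated to a ligand. Because resonance energy transfer requires the donor
and acceptor to sit within about 10 nm, the acceptor/donor emission ratio —
the BRET ratio — is a direct, live-cell measure of receptor occupancy. The
package analyses well-level plate tables of such ratios (or of the raw
donor and acceptor counts, from which it computes them) for four designs:

* **saturation**: endpoint ratios over a probe dilution series, with paired
  wells co-treated with a large excess of unlabeled ligand to define
  non-specific binding (NSB);
* **association kinetics**: ratios read every 30 s after probe addition, at
  several probe concentrations, with ligand-free vehicle wells;
* **competition**: endpoint ratios for an unlabeled competitor dilution
  series against several fixed probe concentrations;
* **concentration–response**: a downstream functional readout (for example
  a reporter-gene signal) over an agonist dilution series.

All interfaces accept and report concentrations in nM and times in minutes;
internally concentrations are molar and times minutes, matching the
conventional units of `kon` (M⁻¹·min⁻¹) and `koff` (min⁻¹).

## Models

Everything rests on one-site mass action. For a probe at concentration $L$
with equilibrium dissociation constant $K_D$:

* fractional occupancy $L/(L+K_D)$;
* a **total** saturation well is modelled as
  $\text{baseline} + B_\max \, L/(L+K_D) + m\,L$ and its paired **NSB**
  well as $\text{baseline} + m\,L$, where $m \ge 0$ is the non-specific
  slope. The two well types are fitted **jointly** with shared baseline and
  slope rather than by pointwise subtraction: this uses every well once and
  cannot produce negative "specific" signals.
* an association trace at concentration $L$ follows the mono-exponential
  $B_{eq}(L)\,\bigl(1 - e^{-k_{obs}t}\bigr)$ with
  $k_{obs} = k_{on}L + k_{off}$ and
  $B_{eq}(L) = B_\max L/(L + k_{off}/k_{on})$. A single experiment's traces
  at all concentrations share $k_{on}$, $k_{off}$ and one amplitude
  $B_\max$ (the **global fit**); a shared amplitude is what makes the two
  rate constants separately identifiable from a 20-min window.
* derived kinetic quantities: kinetic $K_D = k_{off}/k_{on}$, association
  half-time $t_{1/2} = \ln 2 / k_{obs}$, and residence time $1/k_{off}$.
* a competition curve at probe concentration $L$ is
  $\text{bottom} + (\text{top}-\text{bottom})/(1 + (I/\mathrm{IC_{50}})^h)$
  with $h = 1$ by default (simple competitive mass action; a
  `free_hill` flag exists). Each fitted IC50 converts to a competitor
  affinity by the Cheng–Prusoff relation
  $K_i = \mathrm{IC_{50}} / (1 + L/K_D)$. Read forwards the relation is
  affine in $L$, so regressing IC50 on probe concentration gives the
  competitor $K_i$ as intercept, $K_i/K_D$ as slope, and intercept/slope as
  an independent estimate of the probe $K_D$.
* concentration–response curves use the standard sigmoid
  $\text{basal} + (E_\max-\text{basal})\,C^h/(C^h + \mathrm{EC_{50}}^h)$,
  reported as pEC50.

## Estimation

Each experiment is fitted separately and parameters are then summarised as
mean ± SEM across experiments — the convention for independent biological
replicates, and the reason a tabulated "kinetic $K_D$" need not equal the
ratio of the tabulated mean rates: the ratio is taken per experiment
*before* averaging.

Nonlinear fits use Levenberg–Marquardt (`minpack.lm::nls.lm`) on residual
functions with box bounds. Affinities and rates are fitted as log₁₀
quantities ($\log_{10} K_D$, $\log_{10} k_{on} \in [3, 12]$,
$\log_{10} k_{off} \in [-5, 2]$, log₁₀ IC50, log₁₀ EC50) for positivity and
conditioning, then back-transformed for reporting. Convergence tolerances
are 10⁻¹² on the objective and parameters; each fit tries a small
deterministic grid of starting values (three starts spread over the
concentration range) and keeps the lowest deviance — there is no randomness
anywhere in fitting. Standard errors come from the Gauss–Newton Hessian at
the optimum; for the IC50-versus-probe regression the probe-$K_D$ estimate
intercept/slope carries a first-order (delta-method) standard error.

Degenerate inputs are flagged rather than guessed at: a flat kinetic trace
returns an unidentifiable rate with `converged = FALSE`; a single-probe
kinetic table is rejected with a pointer to the single-curve fitter; a
displacement fit whose top falls below its bottom is marked non-physical; a
non-positive regression slope yields an undefined probe-$K_D$ estimate.
Zero divisions that would correspond to unphysical parameters
($k_{off} = 0$, $K_D \le 0$) raise errors instead of returning infinities.

Pooling conventions: per-curve $K_i$ values are averaged on the linear
scale and then logged (`pKi = -log10(mean Ki)`); saturation $K_D$ is
averaged in nM on the linear scale; pEC50 and pKi aggregate on the log
scale. `aggregate_parameters()` exposes the choice per parameter. A one-way
fixed-effects ANOVA (`test_probe_dependence()`) checks that pKi does not
depend on which probe (or probe concentration) was used, as expected under
simple competition, and `power_delta_pki()` gives the two-sided
noncentral-*t* power of the between-group design to detect a pKi shift
(with `delta = 0` it returns exactly the significance level, because both
rejection tails are kept).

## The synthetic-data generator

`simulation_design()` + `simulate_plate()` generate plate tables with the
statistical structure of the four designs, so every fitting stage is
testable without laboratory data. Defaults mirror the standard study
conditions: five independent experiments, duplicate wells, saturation
endpoints over 0.1–30 nM probe with paired 100 nM-unlabeled NSB wells,
association reads every 30 s for 20 min at 1–20 nM probe with vehicle
wells, competition at five fixed probe concentrations against a half-log
competitor series, and additive i.i.d. Gaussian noise on the ratio scale.
The default noise SD is 5% of the specific amplitude; raw ratio magnitudes
(baseline 0.05, amplitude 0.02 ratio units) are arbitrary but documented,
and every recovery check is invariant to them. Time zero is the moment of
ligand addition; vehicle correction is applied downstream by
`baseline_correct()`, not at generation. Each experiment draws from its own
derived RNG stream, so enlarging `n_experiments` never perturbs earlier
experiments' data, and a fixed seed reproduces a plate byte-for-byte
through `write_plate_csv()`. `emit_channels()` back-fills donor/acceptor
counts consistent with each ratio for testing the ratio-computation path.

What the generator does **not** emulate: donor (luminescence) decay over
the read window, substrate consumption, plate-position effects,
heteroscedastic noise, or ligand depletion (excess-ligand conditions are
assumed throughout). Parameter recovery on these simulations therefore
demonstrates correctness of the estimators under the stated model, not
robustness to every artefact of real plates.

One consequence of the flat noise model is worth knowing: at the lowest
probe concentrations the specific displacement window shrinks toward the
noise floor ($B_\max L/(L+K_D)$ is ~2× the default noise SD at 0.5 nM probe
with a ~4 nM $K_D$), so per-curve IC50s there are weakly determined, the
IC50-versus-probe regression can be uninformative at the default noise, and
linear averaging of noisy, right-skewed $K_i$ values biases the pooled pKi
downward. Noiseless and low-noise recovery is exact (the test suite checks
recovery to 10⁻⁴ relative), and the delta-method SE on the regression
estimate makes the imprecision visible rather than hidden.

## Worked example

```{r example, eval = FALSE}
# simulate a noiseless association experiment at the co-receptor's rates
design <- simulation_design(
  "association",
  list(rates = kinetic_rates(kon = 7.11e7, koff = 0.26),
       bmax = 0.02, baseline = 0.05),
  probe_concs_nM = c(1, 2.5, 5, 10, 20),
  replicates = 1, noise_sd = 0, n_experiments = 5, seed = 1)
plate <- simulate_plate(design)
fit <- fit_association_global(baseline_correct(plate))
fit$mean[c("kon_per_M_min", "koff_per_min", "kinetic_kd_nM")]

r <- kinetic_rates(fit$mean[["kon_per_M_min"]], fit$mean[["koff_per_min"]])
half_time(1e-9, r)    # association half-time at 1 nM, minutes
residence_time(r)     # 1/koff, minutes
```

## Problem sizes and reproducibility

The packaged analysis scripts (`analysis/01` … `05`) and the acceptance
script (`scripts/acceptance.R`) use the standard design sizes — 5
experiments, 8-point saturation series in duplicate (160 wells), 5-point
kinetic series at 41 timepoints (1,230–2,460 wells), 5 × 12-point
competition grids in duplicate (600 wells) — which fit comfortably in a few
seconds of compute. All randomness flows from a single integer seed through
per-experiment derived streams.

## Known limitations

* One-site binding only: no two-site, cooperative or allosteric models, no
  depletion correction, and no kinetic-competition (competitor-association)
  modelling.
* Unweighted least squares; a well-level variance model could sharpen the
  low-signal competition curves but none is assumed.
* The pooled-pKi convention (linear-mean $K_i$, then log) is one of several
  in use; `aggregate_parameters()` can aggregate on the log scale instead
  where a geometric convention is preferred.
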