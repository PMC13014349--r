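---
title: "NBFR: model, design choices and simulation conditions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{NBFR: model, design choices and simulation conditions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nbfr)
```

This vignette is the package's own account of the science it implements: the
statistical model, the experimental-design algorithm, the optimizer, the
simulation framework used to benchmark everything, and — importantly — the
choices we made where the design was genuinely open, with the reasoning
behind each.

## The problem

Two-photon holographic optogenetics can excite user-selected ensembles of
neurons, but the light is not perfectly confined to a target's soma: opsin in
the proximal dendrites and the finite optical point spread mean that
stimulating at a neuron's centroid often also activates neighbours within
~10–20 µm. We call a neuron's spatial sensitivity profile its *optogenetic
receptive field* (ORF): the scalar evoked fluorescence response as a function
of the 2D stimulation coordinate. If ORFs are known, stimulation sites can be
moved off the centroids to positions that still drive the targets but avoid
the neighbours.

## The NBFR model

Responses to a *J*-target ensemble stimulus are modelled as the sum of the
per-target ORF values plus Gaussian noise (one scalar response per neuron per
trial, e.g. a z-scored evoked dF/F amplitude; how that scalar is derived from
raw traces is an upstream concern — any pre-computed scalar is accepted, and
the simulator produces exactly this quantity). Each ORF is a non-negative
mixture of radial basis functions

$$\phi(x) = \exp\!\big(-\lVert c - x\rVert^q / (2\ell^q)\big)$$

centred at the *stimulation sites themselves* (every retained site within
d = 30 µm of the neuron's centroid). This adaptivity means model complexity
scales with what was actually probed, and a site allocated to neuron *j*'s
grid also informs neuron *i*'s ORF when the two are close — the mechanism
that lets single-trial mapping data support stable fits: spatially
uncorrelated noise is averaged away across nearby sites while the spatially
correlated ORF signal is preserved.

Weights are estimated per neuron by non-negative least squares
(Lawson–Hanson, via `pracma::lsqnonneg`). Non-negativity matters: an
unconstrained fit happily predicts negative responses to out-of-sample
hologram placements, which is physically meaningless and corrupts the
downstream optimization. Rank-deficient designs are permitted — NNLS is still
well defined; when minimizers are non-unique we accept whatever the solver
returns, and our tests assert the *objective value* (checked against an
exhaustive active-set enumeration oracle on small instances), never weight
uniqueness.

### Fit parameters

| parameter | default | units | rationale |
|---|---|---|---|
| length scale ℓ | 6 | µm | between the 5 µm site-separation floor and the ~9 µm population point-spread half-width; the basis must bridge adjacent retained sites without oversmoothing |
| exponent q (fit) | 2 | — | Gaussian basis; the only case with an analytic optimization gradient |
| inclusion radius d | 30 | µm | matches the radius at which single-target responses are still observed |
| excitability threshold | 0.1 | normalized response | neurons whose fitted ORF never reaches 0.1 at any basis centre are flagged non-excitable and excluded from optimization and ensemble selection |

The fitted residual SD `noise_sd` is retained per neuron for diagnostics
only; nothing downstream consumes it.

## Mapping-protocol design

Per neuron, a 5 × 5 grid of candidate sites spans ±16 µm around the centroid
at 8 µm steps (25 sites). Sites within 5 µm of another *neuron's* grid sites
are removed in a seeded random sequential pass (same-grid pairs are exempt);
the retained sites are then batched into 10-target trials such that every
target is ≥ 30 µm from every target of the immediately preceding trial, so
evoked calcium transients decay before a neighbourhood is revisited.

Open choices made here:

* **Inter-trial spacing = 30 µm.** The constraint distance is not an
  experimentally fixed constant; we default it to the same 30 µm
  response-neighbourhood radius used everywhere else. Configurable.
* **Previous-trial-only history.** The spacing constraint applies to the
  immediately preceding trial only, the literal reading of the design; a
  longer history would trade trial-count for cleaner baselines.
* **Relaxation, never failure.** Trials are drawn by rejection sampling
  (up to 1000 draws); when the remaining pool cannot satisfy the constraint
  (common for the final few trials), the sites farthest from the previous
  trial are taken greedily and the relaxation is counted in
  `protocol$n_relaxed`. A protocol is always produced.
* **The final short trial is emitted as-is**, not padded: padding would
  re-stimulate sites and bias single-trial estimates.

Because overlapping grids share sites, the number of trials grows sublinearly
with population size at fixed FOV; at the default density (300 neurons in a
411 µm square) a mapping run needs fewer trials than neurons. At low density
(≤ ~200 neurons in that FOV) grids barely overlap and the trial count is
necessarily close to 2.5 per neuron — sublinearity is a density phenomenon,
not an unconditional guarantee.

## Stimulus optimization

The objective is the evoked activity summed over targets minus that summed
over non-targets, with optional per-neuron importance weights α: α = 0
removes a poorly characterized neuron from consideration entirely, large α
forces a neuron's activation or avoidance. For q = 2 the gradient is
analytic; note the exponent carries the *squared* distance,
$\exp(-\lVert x_{nm}-x^j\rVert^2/(2\ell^2))$ — the true gradient of the
Gaussian basis, which our tests verify against central finite differences to
relative error below 1e-5. For q > 2 the optimizer transparently falls back
to central finite differences and says so.

Each hologram ascends independently (the objective is separable across
targets) from the target's somatic centroid, with backtracking: the 1 µm
step is halved until the objective does not decrease, giving a monotone
per-target trace and the guarantee that the optimized pattern is never worse
than somatic *under the model*. Iteration stops when the per-step objective
change falls below 1e-6 or after 200 iterations; these are fixed, logged
stand-ins for what an experimenter would tune live while watching the trace.
An optional displacement cap (off by default; 16 µm — the grid extent — is a
sensible value) prevents runaway repositioning. When a weakly responsive
target is surrounded by strongly responsive non-targets the optimum genuinely
lies outside every ORF: the optimizer will park the hologram in empty space
and the predicted target activation reports ≈ 0, which callers should treat
as an abort-stimulation signal rather than a usable pattern.

Numerical details: per-hologram evaluations use only bases within 80 µm of
the current position (contributions beyond are below exp(−50)); the
neighbourhood is refreshed whenever the hologram drifts more than 20 µm.
Population fits likewise drop trials with no target within d + 25 µm of the
neuron (all basis values below 2e-4 there); the exact, untruncated path is
used by the single-neuron functions and by every oracle test.

## The simulator

The simulator generates the study conditions end-to-end, so every module is
testable without microscope data:

* **Centroids** uniform in a 411 × 411 µm² FOV; default N = 300.
* **Ground-truth ORFs**: per neuron, 1–4 super-Gaussian components (q = 4 —
  sharper-edged, flat-topped profiles than the Gaussian fit basis; the
  exponent mismatch between truth and model is deliberate and preserved),
  centres uniform in a 10 µm disc around the soma, widths uniform in
  4–10 µm, positive weights, the whole mixture rescaled to a continuum peak
  of exactly 1 (grid search plus Nelder–Mead refinement). These ranges are
  our choice where no measured values exist; they reproduce the qualitative
  phenomenology that motivates the method — many neurons respond at ≥ 0.5 of
  peak more than 15 µm from their centroid, but not all — and they are all
  configurable.
* **Responses**: noiseless drive plus i.i.d. Gaussian imaging noise,
  ν = 0.25 of the normalized ORF peak.
* **Ensembles**: a uniform centre neuron, then members drawn without
  replacement with probability ∝ exp(−λ·distance); λ = 1 gives compact,
  λ = 0.01 diffuse ensembles. Benchmarks default to diffuse sampling — with
  compact ensembles most "off-target" light lands on other ensemble members,
  so diffuse ensembles are both the harder and the more informative case.
* **Recurrence (optional)**: a zero-inflated exponential connectome
  (connection probability 0.05, mean strength γ), one synchronous round:
  each neuron spikes with probability `plogis(0.85·drive − 3)` and delivers
  its outgoing strengths to partners. With γ → 1 the contamination reaches
  the scale of the direct drive itself and ORF fitting degrades accordingly.
* **Scoring**: a neuron counts as activated when its *noiseless ground-truth*
  drive reaches τ = 0.5 (half the normalized peak). Scoring is FOV-wide and
  always uses ground truth; fitted models are used only for optimizing.
  Recurrence is disabled during scoring so the measured off-target effects
  isolate direct optical off-target stimulation. τ is the single most
  benchmark-sensitive free parameter; it is surfaced in the configuration
  and recorded with every benchmark manifest.

What the simulator does **not** emulate: calcium-indicator kinetics and
frame-rate temporal structure, FOV motion (in real preparations the dominant
performance limiter), inhibition, 3D optics, and laser-power effects. Tests
passing here therefore demonstrate correctness of the algorithms under the
stated generative model, not in-vivo performance.

## Evaluation conventions

The off-target ratio (OTR) is activated non-targets per activated target.
When an ensemble activates no target the ratio is undefined; we exclude such
ensembles from means and report their count rather than letting infinities
poison averages. Benchmark sweeps average ensembles within a simulation
first, then across simulations, pairing somatic and optimized conditions on
identical truth, fit and seeds. At γ = 1 in the recurrence sweep the somatic
and optimized conditions are compared by overlapping mean ± 1 SD bands (the
variance across simulations is very large there); at weaker coupling a
paired one-sided t-test is used.

Repetition averaging repeats each trial with independent noise and averages,
shrinking the noise SD by 1/√reps. The repetition-scaling test pairs the
repetition levels on shared noise prefixes (level r uses the first r of 8
pre-drawn noise matrices), a common-random-numbers device that removes
between-level sampling noise from a monotonicity comparison.

## Problem sizes used by the shipped tests

Unit tests run on deliberately small scenes (tens of neurons, 100–200 µm
FOVs) with brute-force oracles; the benchmark tests run 20 simulations per
condition at the full default conditions (300 neurons, 411 µm FOV), and the
recurrence sweep runs 20 simulations at each of four coupling strengths.
These sizes are the package's chosen trade-off between statistical
resolution of the benchmark bands and keeping the whole suite comfortably
runnable on a laptop; all of them are parameters, not constants.

## Known limitations

* 2D only; extending the bases to 3D is straightforward but the optimizer
  would remain per-plane.
* No laser-power or per-neuron hard activation constraints in the objective;
  the abort-stimulation behaviour above is the practical consequence.
* The convergence rule (tolerance on the objective change) is a fixed proxy
  for live operator judgment.
* Static ORFs: slow drifts in excitability or expression are not modelled;
  in practice one would rescale ORF amplitudes online against recent
  transients.
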