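---
title: "Inferring transcriptional bursting from MS2 traces"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring transcriptional bursting from MS2 traces}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(msburst)
```

## The model

In early fly embryos, transcription of patterned genes such as
*even-skipped* occurs in stochastic bursts. The classical telegraph model
describes a promoter switching between an inactive (OFF) and an active
(ON) state at rates $k_{on}$ and $k_{off}$ (both min$^{-1}$); while ON it
loads polymerases at rate $r$ (AU/min). The mean initiation rate is

$$\bar{R} = r\,\frac{k_{on}}{k_{on}+k_{off}},$$

so an enhancer can raise output through burst frequency ($k_{on}$),
duration ($k_{off}^{-1}$), amplitude ($r$), or any combination.

Because transcription in nc14 happens after DNA replication and sister
chromatids stay paired, each fluorescent MS2 spot reports **two**
promoters. `msburst` therefore works with a three-state chain over
$\{$OFF, ON$_1$, ON$_2\}$ — 0, 1 or 2 active sister promoters. Two
independent identical promoters give the generator of
`build_sister_chain()`; a fitted chain is reduced back to effective
two-state parameters with the aggregation formulas

$$k_{on} = q_{0\to1} + q_{0\to2}, \qquad
k_{off}^{-1} = \left(\tfrac{1}{p_{off}} - 1\right) k_{on}^{-1}, \qquad
r = \frac{p_1 r_1 + p_2 r_2}{p_1 + p_2},$$

where $p_{off}, p_1, p_2$ are stationary occupancies
(`aggregate_burst_params()`, `to_burst_params()`).

## Why a compound-state HMM

An MS2 trace does not report the instantaneous promoter state: every
loaded polymerase keeps contributing fluorescence while it elongates
through the transcript (~140 s for the MS2::yellow unit, `t_elong`). The
observed signal is the promoter activity convolved with this memory
window, so the emission at frame $t$ depends on the last
$w = \mathrm{round}(t_{elong}/\Delta t)$ promoter states ($w = 7$ at the
20 s inference grid). The cpHMM makes this Markovian again by taking the
whole window as the hidden state: $K^w = 3^7 = 2187$ compound states,
each with $K$ successors under the shift map
(`build_state_space()`). Emissions are Gaussian around

$$\mu(s) = \sum_{i=0}^{w-1} \kappa_i\, r_{s_i}\, \frac{\Delta t}{60},$$

with a shared noise s.d. $\sigma$. Filtering and smoothing are exact
over the compound chain (`forward_backward()`, implemented in C++);
Baum-Welch EM updates the promoter transition matrix from expected
counts and the initiation rates and $\sigma$ by weighted least squares,
with the OFF rate pinned to 0 (`em_fit()`).

## Parameters that matter

| parameter | default | units | meaning |
|---|---|---|---|
| `t_elong` | 140 | s | elongation memory of the reporter |
| `dt_frame` / `grid_dt_s` | 16.8/19.5 native, 20 inference | s | frame intervals |
| `sigma_noise` | 1.5 | AU | Gaussian imaging noise of the generator |
| `k_on` | 0.5-1.5 | min$^{-1}$ | burst frequency (wild-type range) |
| `k_off` | 0.5 | min$^{-1}$ | burst-termination rate, ~constant |
| `r` | 5-10 | AU/min | burst amplitude (wild-type range) |
| mean fluorescence | 2-15 | AU | wild-type output range |
| bin size | ~40 traces / ~2500 pts | — | one cpHMM inference unit |

The generator's parameter map (`params_from_target()`) is affine in mean
fluorescence between the range endpoints: nuclei that are brighter on
average get proportionally higher $k_{on}$ and $r$ while $k_{off}$ stays
fixed — the "unified bursting strategy" the inference should, and does,
recover. After the affine map the initiation rates are rescaled so the
model's steady-state mean fluorescence matches the target exactly. A
consequence worth knowing: since mean output is
$r(1-p_{off})\,t_{elong}/60$ and $1-p_{off}$ rises only 1.5x across the
range, the rescale stretches the realized $r$ span beyond its affine
endpoints (~5x over the full 2-15 AU range). The monotone trends, not
the functional form or the fold factors, are the modeled claim, and the
package's verification checks therefore compare recovered fold changes
to the generator's own per-bin truth.

## The synthetic embryo generator

`generate_dataset()` emulates nucleus-level live-imaging tables: per
genotype it lays out stripe regions along the AP axis (stripe 0 at ~20%,
stripe 1 at ~30%, stripe 2 at ~40% embryo length; the stripe 1-2
interstripe between them), jitters stripe centers across embryos
(s.d. 0.005 EL) so pseudo-stripe registration is non-trivial, samples
active and inactive nuclei, and renders each active nucleus's trace from
its own Gillespie path. Ectopic regions (S0, S1_2) get a 0.6x mean-output
scale — what is known is only that ectopic output is lower on average,
so the factor is a tunable, not a claim; likewise the stripe half-widths
(0.02 EL, 0.03 EL for the interstripe) and the 0.8 active fraction.

What the generator does **not** emulate: transcription-factor gradients,
nuclear movement (AP positions are static), photobleaching, detection
dropouts, and trace-to-trace noise heteroscedasticity. Passing tests
therefore show that the inference machinery recovers known kinetics from
data with the assumed structure — not that real embryos satisfy those
assumptions.

## Numerical choices

* **Frame convention.** Rendered frame $j$ sits at $t = j\,\Delta t$ and
  integrates promoter activity over $((j-1)\Delta t, j\Delta t]$ with
  dwell-time weighting, so a promoter that switches ON at $t=0$ reaches
  its plateau exactly at $t_{elong}$, and renderer frames align
  one-to-one with cpHMM emissions.
* **Early frames.** The first $w-1$ frames of a trace use a truncated
  kernel over the available history rather than being discarded.
* **Scaling.** The forward pass is rescaled per frame; emission
  likelihoods are column-rescaled in log space with a floor at
  $e^{-700}$ so that near-noise-free traces cannot zero the recursion.
* **Rate conversion.** $\hat{Q} = \log(A)/\Delta t$ via
  eigendecomposition, with negative off-diagonals clipped and the
  diagonal rebalanced; if the logarithm is not real the first-order
  $(A - I)/\Delta t$ is used and recorded in `rate_method`.
* **Initialization and convergence.** Dirichlet diagonal-biased
  transition rows, initiation rates from fluorescence quantiles, noise
  from first differences; restarts with jitter; convergence at relative
  log-likelihood change below `tol` (default $10^{-5}$).
* **Degenerate inputs.** $A = I$, reducible generators, all-OFF
  occupancies and $p_{off} \in \{0, 1\}$ raise informative errors rather
  than returning silent nonsense.

## Design choices that were genuinely open

* The emission kernel is uniform by default (each polymerase contributes
  full fluorescence for exactly `t_elong`); a fractional first weight is
  exposed for the gradual MS2-loop rise but not used by default.
* The fitted chain is a general 3-state Markov chain — no
  independent-sister constraint and no $r_2 = 2 r_1$ tie. The
  aggregation formulas assume nothing more, and this keeps the inference
  honest when the truth is not exactly two independent sisters.
* k-means stripe assignment runs per 5-minute window on AP position
  weighted by accumulated output, with 10 restarts; a nucleus's final
  label comes from the window containing the 25-min reference when it is
  active there, otherwise from its majority label (ties to the anterior
  stripe). Manual boundary tables use half-open, anterior-inclusive
  intervals with the stripe 1-2/stripe 2 boundary at 36% EL.
* Bootstrap (resampling traces within a bin) supplies the per-bin
  parameter s.d.; the error-bar estimator behind published figures is
  not stated, so the output records `bootstrap` as the method.
* Nuclei without a stripe label are registered onto pseudo-stripes with
  the offset of the nearest labeled stripe in their embryo.

## Problem sizes

The package's own test and verification runs use desk-scale versions of
the analysis: recovery checks run one bin of 40 traces of ~70 points at
the printed operating points (the full 2187-state, $w=7$ space for the
verification script; a $w=5$ window for the routine test suite), and the
full-pipeline strategy check uses two embryos of 30 active nuclei per
region with a 5-replicate bootstrap. Full-scale runs are a matter of
configuration, not code.

## Known limitations

* Inference is exact but dense in the compound space: $K^w$ is capped at
  2187; longer memories need a coarser grid rather than a larger $w$.
* Parameters are per-bin averages; trace-level random effects are out of
  scope.
* The discrete-time chain approximates the continuous-time promoter:
  within-frame switching mixes emissions, which biases $k_{off}$
  slightly downward at realistic noise. The recovery tests quantify
  this: medians stay within the stochastic tolerances of the study's bin
  sizes.
* Endogenous/ectopic comparison is descriptive (fold changes,
  monotonicity, bootstrap overlay); no formal curve-equality test is
  attempted.

## A worked example

```{r, eval = FALSE}
library(msburst)

# simulate one wild-type-like bin and re-infer its parameters
m <- model_from_burst_params(k_on = 1, k_off = 0.5, r = 7.5)
traces <- lapply(1:40, function(i) {
  path <- simulate_chain_path(m$Q, 24, seed = i)
  render_trace(path, m, n_frames = 70, seed = 1000 + i)$fluo_au
})
space <- build_state_space(3, 7)
fit <- em_fit(traces, space, cphmm_config(n_restarts = 2, seed = 1))
to_burst_params(fit)

# or run the whole synthetic pipeline
cfg <- pipeline_config(genotype = "eveS1null_eveS2Gt", seed = 1)
res <- run_pipeline(cfg)
res$trends$ectopic
```
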