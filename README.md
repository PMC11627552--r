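# msburst

Transcriptional bursting analysis of MS2/MCP live-imaging traces from
early fly embryos — simulation, inference, and pattern-level summaries.

## The problem

Developmental genes like *even-skipped* (*eve*) are transcribed in
stochastic bursts. In the telegraph model a promoter switches OFF→ON at
rate *k_on* (burst frequency), ON→OFF at *k_off* (inverse burst
duration), and initiates polymerases at rate *r* (burst amplitude) while
ON, giving a mean initiation rate

    R̄ = r · k_on / (k_on + k_off).

MS2 imaging reports these dynamics only indirectly: each polymerase
fluoresces for the whole ~140 s it elongates, so the signal is promoter
activity convolved with an elongation memory, and — because sister
chromatids stay paired — each spot contains **two** promoters. `msburst`
implements the resulting three-state (0/1/2 active sisters)
compound-state hidden Markov model (cpHMM): the hidden state is the
window of the last *w* = round(t_elong/Δt) promoter states, emissions
are Gaussian around the kernel-weighted window sum, fitting is exact
Baum–Welch EM over the 3⁷ = 2187 compound states, and fitted chains are
aggregated to effective two-state parameters via

    k_on = q01 + q02,   k_off⁻¹ = (1/p_off − 1)·k_on⁻¹,
    r = (p1·r1 + p2·r2)/(p1 + p2).

Around the estimator the package provides the full analysis pipeline
used for stripe-level bursting studies: a synthetic embryo generator
(genotype-specific stripe patterns, endogenous and ectopic regions,
Gillespie-simulated traces with known truth), interpolation to the 20-s
inference grid, stripe assignment (weighted k-means or manual AP
boundaries, endogenous/ectopic labeling), binning by mean fluorescence
(~40 nuclei / ~2500 points per bin) with per-bin inference and bootstrap
uncertainties, strategy comparison between groups, and pseudo-stripe
registered kymographs.

It is intended for quantitative biologists who want a tested, scriptable
re-implementation of this analysis for simulation studies, method
checks, or their own trace tables (CSV, one row per nucleus per frame).

## A worked example

```r
library(msburst)

# one inference bin at a wild-type operating point
m <- model_from_burst_params(k_on = 1, k_off = 0.5, r = 7.5)  # /min, AU/min
traces <- lapply(1:40, function(i) {
  path <- simulate_chain_path(m$Q, 24, seed = i)              # 24 min
  render_trace(path, m, n_frames = 70, seed = 1000 + i)$fluo_au
})
space <- build_state_space(3, 7)                              # 2187 states
fit <- em_fit(traces, space, cphmm_config(n_restarts = 2, seed = 1))
to_burst_params(fit)
#> burst_params: k_on = 1.169 /min, k_off = 0.486 /min, r = 7.293 AU/min
#>   occupancies: p_off = 0.294, p1 = 0.534, p2 = 0.172
```

The printed numbers are the effective two-state estimates for the bin:
the promoter bursts ~1.2 times per minute, bursts last ~1/0.49 ≈ 2
min, and active promoters gain ~7.3 AU of fluorescence per minute —
recovering the simulated truth (1.0, 0.5, 7.5) within the scatter
expected of a single 40-trace bin.

The full synthetic pipeline (simulate → assign → bin → infer → compare →
kymograph) runs from one config:

```r
res <- run_pipeline(pipeline_config(genotype = "eveS1null_eveS2Gt", seed = 1))
tc <- res$trends$ectopic   # trend curves grouped endogenous vs ectopic
compare_strategies(tc[tc$group == "endogenous", ],
                   tc[tc$group == "ectopic", ])
```

At full defaults this takes tens of minutes on one core; shrink
`n_per_region` and `duration_min` (and `t_elong` for a smaller HMM
window) for a quick look.

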