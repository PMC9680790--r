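# cftrgate

Hidden-state inference for CFTR single-channel gating: classify channel
closings as **permissive** or **nonpermissive** from patch-clamp current
traces alone.

## The problem

CFTR, the ATP-gated chloride channel mutated in cystic fibrosis, cycles
through seven kinetic microstates — five closed (C1a, C1b, C2, C3, C4) and
two open (O1, O2) — with two irreversible steps: ATP hydrolysis (O1 → O2) and
ADP release (C4 → C1a). A closing that reopens in the same open state it
closed from (O1 → C2 … C2 → O1 or O2 → C3 … C3 → O2) is *permissive*: no
nucleotide is exchanged. A closing that closes from O2 and reopens as O1 must
traverse the ADP-release step and is *nonpermissive*. The two kinds are
electrically identical — every closed state conducts nothing — so telling
them apart pinpoints nucleotide-exchange events that no amplifier can see
directly. This matters to anyone studying how mutations, agonists or toxins
alter CFTR's hidden kinetics.

## The method

The trace is modeled as an aggregated hidden Markov model: microstates follow
a discrete-time chain with transition matrix Q = exp(R Δt), where R is the
rate matrix of the gating cycle (master equation dP/dt = P R, ATP-dependent
binding step), and each sample is y_k = A·m(s_k) + n_k with conductance map
m(s) ∈ {0, 1} and Gaussian noise of variance σ². The package

* computes exact posterior marginals p(s_k | y) by the scaled
  forward-backward algorithm (sum-product on the chain factor graph);
* estimates Q, σ² and optionally A by expectation-maximization with
  closed-form M-steps, under a hard constraint to the gating-cycle topology —
  the constraint is what makes electrically identical states identifiable;
* applies the confidence-thresholded MAP rule (argmax posterior where it
  exceeds C, null otherwise), segments the estimated sequence into closings,
  labels them from their flanking open states, and scores detection with
  false-alarm / missed-detection probabilities against simulated ground
  truth;
* ships a kinetic simulator (the default scheme reproduces the wild-type,
  high-open-probability rate table), block-averaging decimation and
  polarity/baseline normalization for raw recordings, and parameterized
  concentration sweeps.

## Worked example

Simulate 200 s of gating at 0.5 mM ATP and 100 Hz, fit the model by EM
without telling it the rate constants, and score closing detection:

```r
library(cftrgate)

sim <- simulate_trace(atp = 5e-4, dt = 0.01, n = 20000,
                      amplitude = 1, sigma2 = 0.02, seed = 11)
fit <- cftr_fit(sim$trace, iterations = 400,
                estimate_amplitude = FALSE, amplitude = 1, seed = 11)
fit
#> Hidden-Markov gating model fit (factor-graph EM)
#>   20000 samples at dt = 0.01 s, 400 EM iterations
#>   amplitude = 1.0000 (fixed), noise variance = 0.02018
#>   final log-likelihood: 7724.3153

gt <- extract_closings(sim$states, cftr_scheme())
score_closings(gt, closings(fit))
#> Nonpermissive-closing detection:
#>   closings: 340 estimated (19 nonpermissive), 338 true (25 nonpermissive)
#>   P_FA = 0.158 (3 false alarms), P_MD = 0.360 (9 missed)

score_closings(gt, closings(fit, threshold = 0.8), confident_only = TRUE)
#> Nonpermissive-closing detection:
#>   closings: 313 estimated (14 nonpermissive), 338 true (25 nonpermissive)
#>   P_FA = 0.143 (2 false alarms), P_MD = 0.520 (13 missed)
```

The fit recovers the noise variance (0.0202 vs. the true 0.02) and finds 340
closings against 338 true ones. Raising the confidence threshold C from 0 to
0.8 discards low-confidence events: false alarms drop while missed
detections rise — the P_FA / P_MD trade-off the threshold exists to control.
`plot(fit)` shows the EM log-likelihood trajectory; `predict(fit, "map")`
returns the thresholded state estimates; `summary(fit)` prints the estimated
transition matrix.

A thin command-line interface wraps the same functions for shell pipelines
(`exec/cftr`): `simulate`, `preprocess` (normalize + decimate),
`fit`, `infer`, `detect`, `evaluate`, `sweep`.

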