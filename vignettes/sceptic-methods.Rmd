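---
title: "Models and methods: information-compressing reinforcement learning on the clock task"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sceptic)
```

## The task and the representation

In the clock task a participant (or simulated agent) chooses *when* to
respond within a `T`-second trial interval (4 s by default; 5 s in the
replication design). Reward probability `p(t)` and magnitude `m(t)` vary
monotonically with the chosen response time, so the decision space is a
one-dimensional continuum of options rather than a small set of arms.

SCEPTIC represents this continuum with `B = 24` Gaussian radial basis
functions (RBFs) spaced evenly over `[0, T]`. Element `b` has a temporal
receptive field

$$\varphi_b(x) = \exp\!\left[-\frac{(x-\mu_b)^2}{2 s_b^2}\right],$$

and the learned value function is the weighted sum of the unit-height
elements, $V(x) = \sum_b w_b\,\varphi_b(x)$. The basis variance $s_b^2$ is
not a free parameter: it is chosen by 1-D root-finding so that two adjacent
*density-normalized* elements share 50% of their area (the integral of the
pointwise minimum of the two densities). For the default geometry this gives
$s_b \approx 0.129$ s. The choice rule discretizes the interval into 100-ms
bins (40 bins at `T = 4`), and responses are sampled from a softmax over the
bin values, $p_j \propto \exp(V_j/\beta)$: higher temperatures $\beta$ make
choices more stochastic.

Credit assignment is local but generalizing. Feedback obtained at response
time `t` spreads to nearby times through a Gaussian temporal-generalization
function `g` of variance $s_g^2$ (equal to the basis variance by default).
The *eligibility* of element `b` is the shared area between `g` and the
element's density-normalized receptive field,
$e_b = \int \min[g(\tau), \varphi_b(\tau)]\,d\tau \in [0, 1]$: it is exactly
1 when the response lands on the element's center and 0 for elements with no
overlap.

## Learning rules

Traditional (full-maintenance) RL updates every eligible element toward the
obtained reward:

$$w_b \leftarrow w_b + e_b\,\alpha\,[\text{reward} - w_b].$$

The information-compressing selective-maintenance rule adds a decay of
*ineligible* weights toward a prior point `h` (0 by default):

$$w_b \leftarrow w_b + e_b\,\alpha\,[\text{reward} - w_b]
      - \gamma\,(1 - e_b)\,(w_b - h).$$

With $\gamma = 0$ the two rules coincide exactly — the package tests this as
a bit-level identity. Because unchosen alternatives are forgotten, the
weights track *preferences* rather than converging estimates of the reward
rate.

The information content of the value map is the Shannon entropy (log10) of
the normalized weights, $H = -\sum_b \tilde w_b \log_{10} \tilde w_b$.
Weights are normalized only for this computation. Pre-update entropy is
aligned with the decision phase of a trial; the feedback-driven entropy
change $\Delta H$ is aligned with feedback. Under selective maintenance,
successful learning compresses the map ($H$ falls as one region dominates);
under traditional RL the entropy of the map stays high. The working-memory
comparator (`wm_state()`, `wm_update()`, `wm_entropy()`) stores the last
`k = 4` choices as a sum of unit-height Gaussians projected onto the same
basis, plus a parallel reward/omission buffer; its information content is
the sum of the two normalized buffer entropies, and it has no free
parameters.

## Parameters

| Parameter | Meaning | Range | Default cohort mean |
|---|---|---|---|
| `alpha` | learning rate | (0, 1) | 0.10 |
| `beta` | softmax temperature (points) | > 0 | 5 |
| `gamma` | selective-maintenance (decay) rate | [0, 1] | 0.15 |
| `h` | decay target (points) | free | 0 |

`beta` is on the scale of the value function, which with the default reward
schedules (expected values of 25–65 points) spans roughly 0–60 points; a
temperature of 5 therefore yields strongly value-guided but non-degenerate
choice. The cohort defaults were fixed by pilot simulation as the regime in
which agents display the task-typical behavioral signature — early
exploration with large RT swings, later exploitation of the subjective value
maximum, declining value entropy on learnable contingencies — before any
downstream analyses were run, and they are deliberately not tuned per
analysis.

## The synthetic task environment

Because no behavioral data ship with the package, the `clock_task` module
*is* the study population. `make_contingency()` implements the four reward
regimes with a simple affine family (the original stimulus tables are not
public): IEV/DEV have affine increasing/decreasing expected value; CEV and
CEVR hold expected value constant at 40 points while trading probability
against magnitude in opposite directions; `p(t) = ev(t)/m(t)` stays inside
[0.267, 0.8], so the nominal [0.05, 0.95] clip never engages. Any other
schedule satisfying the monotonicity invariants can be supplied via
`ev_params`. Session presets reproduce the three designs (8 × 50 trials at
4 s; 8 × 63; and the 240-trial, 5-s reversal design with unsignaled
contingency switches at trials 41, 81, 121, 161 and 201 — six 40-trial
blocks). Reversals never reset the agent. Initial weights default to a
uniform random prior on [0, 1] point (an all-zero init is available); with
either init, an uninformed map is assigned the maximal entropy
$\log_{10} B$, because zero evidence means all options compete equally.

`synth_neural()` emulates trial-aligned, feedback-locked deconvolved
activity: a chosen latent signal (entropy change by default) is z-scored
across trials and multiplied by a smooth effect curve over peri-feedback
time, plus subject intercepts and Gaussian noise. What these synthetic data
share with real recordings is exactly the trial-by-time-by-signal structure
the analysis code consumes; they have no spatial correlation, no
autocorrelated noise, and no hemodynamic confounds, so passing tests
demonstrate correctness of the dataset construction and model-selection
logic, not robustness to those real-data features.

## Fitting

Subject parameters are estimated on unconstrained scales (logit for `alpha`
and `gamma`, log for `beta`) by MAP with a Laplace approximation: multistart
BFGS (5 starts) maximizes the log-posterior, and posterior SDs come from the
inverse Hessian at the mode. The population level is an empirical-Bayes
loop: alternate subject MAP fits under the current Gaussian population
prior with moment updates (population mean = mean of modes; variance = mean
posterior variance + variance of modes), until the population means move
less than a relative 1e-6 or 50 iterations elapse. After the first
iteration, subject fits are warm-started from their previous modes. This is
a deliberately transparent stand-in for heavier variational machinery with
the same shrinkage structure; it converges in ~20 iterations on a 40 × 400
cohort. For fixed-effect comparisons across subjects,
`refit_at_group_means()` freezes the parameters at the population means and
replays each subject's own choices, recomputing only the latent states.

The likelihood replays the logged choice/outcome sequence deterministically
(weights re-initialized at zero at each run boundary in the original
designs; carried across runs in the replication design — both are exposed,
since run handling is a genuine free choice). Missed responses (missing RT)
are dropped from the likelihood. The replay loop is compiled (Rcpp); a pure-R
reference implementation (`replay_agent()`) is kept and the two are tested
against each other at 1e-12. Model comparison uses per-subject
`AIC = 2k − 2 logL` summed over subjects; lower is better.

## Numerical choices

* **Eligibility quadrature.** Fixed-grid trapezoidal integration on 20,001
  nodes spanning the interval extended by 4 basis SDs on each side. The
  extension keeps boundary elements effectively untruncated so a centered
  response reaches eligibility 1 (truncating at `[0, T]` would break this at
  the edges); the node count was chosen so quadrature agrees with the
  equal-Gaussian closed form $2\Phi(-\delta/2s)$ to below 1e-6.
* **Bin conventions.** Bin representative time is the bin center
  `(j + 0.5) * 0.1` s (0-based `j`); RTs map to bins by `floor(rt / 0.1)`
  clamped to the interval; rewards are computed from the continuous RT. The
  simulation and likelihood evaluate eligibility at the bin centers (exact
  for package-generated data, whose RTs are bin centers).
* **Ties and degenerate inputs.** `rt_vmax` breaks value ties toward the
  earliest bin; the softmax subtracts the maximum before exponentiating;
  all-zero weight vectors have entropy $\log_{10} B$ (value map) or 0
  (WM buffers, which hold no items when empty).
* **KLD histories.** The family of RT-divergence statistics is built
  by turning each RT window into a normalized mixture of unit-height
  Gaussians of variance $s_g^2$ on the bin grid, floored at 1e-6 and
  renormalized; three window presets (`behavioral`, `fmri`, `meg`) encode
  the three published window recipes, and the bandwidth is exposed because
  the original smoothing is unspecified.
* **Survival datasets.** Half-open `[start, stop)` 100-ms bins in
  milliseconds over the 1000–3500-ms modeled window (front/back censoring of
  1000/500 ms); the event falls in the bin whose `(start, stop]` span
  contains the RT, pre-window responses contribute no records, post-window
  responses are fully censored.
* **Neural design.** The double-gamma HRF peaks at 6 s with a 16-s
  undershoot at ratio 1/6 (implementation defaults, exposed); parametric
  values are mean-centered before convolution; the high-pass filter is a
  Gaussian-weighted running-line detrend with SD `1/(2 × 0.008 Hz)` applied
  identically to data and design (a Butterworth variant is behind a flag);
  epoch grids are anchored at feedback onset (the alternative TR-phase
  anchoring was rejected for determinism of the grid).

## Scales used by the shipped checks

The test suite and acceptance script run the analyses at desk scale, chosen
as the smallest sizes at which the qualitative claims are stable:
50-replicate majority tests for entropy dynamics and RT shifts (100-trial
sessions), a 40-subject × 400-trial cohort for parameter recovery, and
50-replicate model-recovery studies with 6-subject cohorts (200 behavioral
trials; 100 trials with 9 peri-feedback time points for the neural
comparison, noise SD 0.5). Model-recovery fits use a single
empirical-Bayes round under a weak prior — AIC needs comparable likelihood
optima, not converged population moments.

## Known limitations

* The affine contingency family preserves the four qualitative regimes but
  is not the original stimulus schedule; quantitative behavior (e.g. points
  earned) is not comparable to the human studies.
* MAP + Laplace underestimates posterior uncertainty relative to full
  variational or MCMC treatments; the SDs feed only the empirical-Bayes
  moments, not inference.
* Mixed-effects estimation (multilevel survival and regression models) is
  intentionally delegated: the package builds engine-ready datasets and AIC
  bookkeeping around plain fixed-effects fits with subject intercepts.
* The WM comparator is implemented as specified for entropy and regression
  analyses but is not wired into the choice rule; it models a memory
  process, not a policy.

## A worked micro-example

```{r example, eval = FALSE}
cfg <- basis_config()
agent <- agent_params(alpha = 0.1, beta = 5, gamma = 0.3)
sim <- run_agent(cfg, agent, make_contingency("DEV"), n_trials = 100,
                 seed = 1)
median(sim$rt[1:10]) - median(sim$rt[91:100])  # positive: earlier responding
autoplot(sim)
```
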