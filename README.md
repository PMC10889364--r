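# sceptic

Simulation, hierarchical fitting, and analysis-dataset construction for the
**SCEPTIC** family of reinforcement-learning models of the continuous-time
*clock task* — for computational cognitive scientists and neuroimaging
analysts who want a fully tested, self-contained implementation of the
information-compressing (selective-maintenance) model, its traditional-RL and
working-memory comparators, and the behavioral/neural dataset builders that
surround them.

## The problem

In the clock task the choice is *when* to respond within a 4-s interval;
reward probability and magnitude vary monotonically with the chosen response
time (four regimes: IEV, DEV, CEV, CEVR). SCEPTIC represents the interval
with B = 24 Gaussian radial basis functions,

    φ_b(x) = exp[ −(x − μ_b)² / (2 s_b²) ],        V(x) = Σ_b w_b φ_b(x),

chooses among 100-ms bins by softmax, p_j ∝ exp(V_j / β), and assigns credit
through a Gaussian temporal-generalization function: the eligibility of
element b is the shared area e_b = ∫ min[g(τ), φ_b(τ)] dτ ∈ [0, 1] between
the (density-normalized) generalization curve centered on the response and
the element's receptive field. Traditional RL updates

    w_b ← w_b + e_b α [reward − w_b],

while the information-compressing rule additionally lets unchosen options
decay toward a prior h (0 by default):

    w_b ← w_b + e_b α [reward − w_b] − γ (1 − e_b)(w_b − h).

The key latent signals are the value-map entropy
H = −Σ w̃_b log10 w̃_b (decision-aligned), its feedback-driven change ΔH, and
RT_Vmax, the response time of the value maximum. Selective maintenance
compresses the value map as learning succeeds — entropy falls and behavior
shifts from exploration to exploitation — whereas traditional RL keeps
entropy high; a buffer-based working-memory comparator (`wm_state()`,
`wm_entropy()`) provides the third account.

The package also ships the surrounding machinery: the synthetic task
environment and agent cohorts (`make_contingency()`, `session_design()`,
`generate_cohort()`), empirical-Bayes hierarchical fitting with group-mean
refits (`fit_population()`, `refit_at_group_means()`), AIC model comparison
(`compare_models()`), model-free behavioral statistics (`rt_swings()`,
`kld_rt_history()`, `buffer_regression_dataset()`), within-trial survival
datasets with time-varying value (`survival_dataset()`), and fMRI-style
regressor construction and epoching (`hrf()`, `peak_renormalized_regressor()`,
`highpass()`, `epoch_feedback()`, `model_comparison_dataset()`).

## Worked example

```r
library(sceptic)

cfg   <- basis_config()                       # 24 RBFs, 40 bins on [0, 4] s
agent <- agent_params(alpha = 0.1, beta = 5, gamma = 0.3)
sim   <- run_agent(cfg, agent, make_contingency("DEV"),
                   n_trials = 100, seed = 1)

median(sim$rt[1:10])      # 2.40  -- early: exploring the interval
median(sim$rt[91:100])    # 0.75  -- late: exploiting early responses (DEV)
mean(sim$entropy[11:20])  # 0.962 -- many competing options early
mean(sim$entropy[91:100]) # 0.608 -- compressed value map late
```

The agent learns that decreasing-expected-value (DEV) rewards favor early
responses: the median RT drops from 2.40 s to 0.75 s, and the entropy of the
learned value map falls from 0.96 to 0.61 log10 units as selective
maintenance prunes unchosen options. The per-trial log carries the latent
signals used in downstream analyses:

```r
sim[96:100, c("trial", "rt", "reward", "entropy", "entropy_change", "rt_vmax")]
#>   trial    rt reward entropy entropy_change rt_vmax
#>      96  0.75    0     0.640        -0.0212    0.65
#>      97  0.75  131.    0.619         0.0225    0.65
#>      98  0.85    0     0.641        -0.0118    0.75
#>      99  0.75    0     0.630        -0.0215    0.75
#>     100  0.75    0     0.608        -0.0216    0.75
```

A full hierarchical analysis chains the same verbs:

```r
co  <- generate_cohort(cohort_spec(n_subjects = 40),
                       session_design("fmri_original"), seed = 11)
fit <- fit_population(co, "selective")
glance(fit)                       # population moments, summed AIC
lat <- refit_at_group_means(co, fit, "selective")
surv <- survival_dataset(lat)     # engine-ready within-trial hazard table
```

Thin command-line wrappers over these functions live in `inst/cli/`
(`simulate.R`, `cohort.R`, `fit.R`); all are seed-deterministic.

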