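# shared fixtures, built once per test run
test_cfg <- basis_config()

# a small deterministic forced choice/outcome sequence on the default grid
forced_sequence <- function(n, seed, cfg = test_cfg) {
  set.seed(seed)
  list(rt = cfg$bin_centers[sample.int(cfg$n_bins, n, replace = TRUE)],
       reward = stats::rbinom(n, 1, 0.5) * stats::runif(n, 20, 120))
}

# closed-form shared area of two equal-width normal densities d apart
overlap_closed_form <- function(d, s) 2 * stats::pnorm(-d / (2 * s))
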