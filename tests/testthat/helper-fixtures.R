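# shared fixtures: the published truth set and a reduced trial design used to
# keep the unit-level fitting tests fast (2 cohorts, 4 subjects each, 7 days)

pub <- published_params()

tiny_design <- function(doses = c(50, 400), n_active = 3L, n_placebo = 1L,
                        n_days = 7L) {
  default_design(
    cohorts = data.frame(dose = doses, n_active = n_active,
                         n_placebo = n_placebo),
    n_days = n_days,
    day1_times = c(0, 1, 2, 4, 8, 12, 24),
    day14_times = c(0, 2, 4, 8, 12, 24, 48, 96),
    trough_days = seq(2L, n_days - 1L)
  )
}

tiny_trial <- function(seed = 1, iiv = FALSE, noise = FALSE, ...) {
  suppressWarnings(
    synthesize_trial(tiny_design(...), pub, iiv = iiv, noise = noise,
                     seed = seed))
}

# independent Emax/sigmoid arithmetic used as hand oracles
emax_val <- function(x, emax, x50) emax * x / (x50 + x)
sigmoid_val <- function(x, rmax, x50, g) rmax * x^g / (x^g + x50^g)
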