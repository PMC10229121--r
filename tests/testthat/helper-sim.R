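# Shared fixtures for simulation-heavy tests: a reduced scan cadence keeps
# repeated simulate -> quantify loops fast without touching the stoichiometry
# model (every scan carries the full C4+1 quartet regardless of cadence).

fast_cfg <- function(...) {
  acquisition_config(scan_interval = 15, include_ms1 = FALSE, ...)
}

# mixture with distinct, strictly positive stoichiometries per degree
test_mixture <- function(abundance = c(40, 25, 15, 10, 6, 4)) {
  pi <- rbind(c(0.70, 0.20, 0.08, 0.02),
              c(0.55, 0.25, 0.13, 0.07),
              c(0.40, 0.30, 0.18, 0.12),
              c(0.30, 0.30, 0.22, 0.18),
              c(0.20, 0.28, 0.27, 0.25),
              c(0.10, 0.22, 0.30, 0.38))
  mixture_spec(abundance, pi)
}

# recovered-vs-truth absolute errors (percentage points) for one run
stoich_abs_error <- function(per_run, mix) {
  truth <- 100 * mix$pi
  me <- c("me0", "me1", "me2", "me3")
  err <- abs(as.matrix(per_run[order(per_run$acetyl_degree), me]) -
               truth[per_run$acetyl_degree + 1, ])
  err
}
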