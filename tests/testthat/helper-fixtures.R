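# Shared fixtures: parameter ranges for property sweeps and a small
# Latin-hypercube sampler. Ranges bracket the model's published constants
# (metabolic rate 2-7 mmHg/s, depletion 15.3-160 mmHg/s, the two
# cell-type ROS presets, tensions up to the 160 mmHg interface value).

lhs_draw <- function(n, ranges, seed = 42L) {
  set.seed(seed)
  k <- length(ranges)
  u <- if (requireNamespace("lhs", quietly = TRUE)) {
    lhs::randomLHS(n, k)
  } else {
    # stratified fallback with the same marginal coverage
    sapply(seq_len(k), function(j) (sample(n) - stats::runif(n)) / n)
  }
  out <- sapply(seq_len(k), function(j) {
    rg <- ranges[[j]]
    rg[1] + u[, j] * (rg[2] - rg[1])
  })
  colnames(out) <- names(ranges)
  as.data.frame(out)
}

ros_ranges <- list(cp = c(0.8e-4, 1e-3), k_ROS = c(0.8e-3, 1e-2),
                   S_ROD = c(15.3, 160), ps = c(0.5, 160))

survival_ranges <- list(ps = c(0, 160), dose = c(5, 20),
                        dose_rate = c(40, 120), S_ROD = c(15.3, 160))

oxygen_ranges <- list(Sm = c(2, 7), p_air = c(120, 200),
                      D_sph = c(1.5e-5, 3e-5), D_med = c(2e-5, 3.5e-5),
                      R = c(0.3, 0.7), H = c(4, 8))

fig1_params <- function(...) flash_params(R = 0.5, H = 6, D_sph = 2.2e-5,
                                          D_med = 2.7e-5, p_air = 160,
                                          Sm = 4.2, S_ROD = 160, ...)
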