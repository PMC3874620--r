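# shared fixtures: packaged defaults and the calibrated baseline trajectory
default_params <- function() load_parameters()

default_traj <- function() generate_trajectory(seasonal_model())

pct_matrix <- function(p5, mean, p95) {
  matrix(c(p5[1], mean[1], p95[1], p5[2], mean[2], p95[2]), 3L, 2L,
         dimnames = list(c("p5", "mean", "p95"), c("men", "women")))
}

# random but valid model inputs for property-style checks
random_inputs <- function(n, seed = 42L) {
  set.seed(seed)
  data.frame(
    I_r = runif(n, 5, 100), I_a = runif(n, 0, 20),
    F_i = runif(n, 10, 1200), L_r = runif(n, 30, 150),
    L_a = runif(n, 5, 120), c_f = runif(n, 0.5, 4),
    level = runif(n, 0, 60)
  )
}
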