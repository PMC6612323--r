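# Shared model fixtures, built in code.

# Two-population model with symmetric coupling (d = (1, 1)).
n2_model <- function(gamma12, gamma21 = gamma12, d2 = 1, delta = 0.1) {
  taxis_model(d = c(1, d2),
              gamma = rbind(c(0, gamma12), c(gamma21, 0)),
              delta = delta)
}

# Three-population template behind the regime map and the bifurcation
# sweeps: d2 = d3 = gamma21 = gamma31 = gamma32 = 1, gamma13 = -1.
n3_template <- function(gamma12, gamma23, delta = 0.1) {
  taxis_model(d = c(1, 1, 1),
              gamma = rbind(c(0, gamma12, -1),
                            c(1, 0, gamma23),
                            c(1, 1, 0)),
              delta = delta)
}

# Single-cosine-mode perturbation of the homogeneous state along a given
# population weight vector, with exact unit mass per population.
cosine_ic <- function(grid, N, m, eps, weights = rep(1, N)) {
  u <- sapply(seq_len(N), function(i)
    1 + eps * weights[i] * cos(2 * pi * m * grid$x))
  population_state(u, grid)
}

# Fitted exponential rate of the kappa-mode amplitude of population 1
# along a trajectory (linear-regime growth measurement).
fitted_mode_rate <- function(traj, m) {
  grid <- traj$grid
  cosv <- cos(2 * pi * m * grid$x)
  sinv <- sin(2 * pi * m * grid$x)
  amp <- vapply(traj$states, function(u) {
    sqrt(mean(u[, 1] * cosv)^2 + mean(u[, 1] * sinv)^2)
  }, numeric(1))
  unname(coef(lm(log(amp) ~ traj$times))[2])
}
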