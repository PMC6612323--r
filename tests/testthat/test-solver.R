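test_that("nonlocal average preserves constants, mass, linearity, and
           damps cosine modes by the sinc factor", {
  g <- spatial_grid(128)
  expect_equal(spatial_average(rep(2.5, g$n), 0.1, g), rep(2.5, g$n),
               tolerance = 1e-14)
  u <- 1 + 0.7 * cos(2 * pi * 3 * g$x) + 0.2 * sin(2 * pi * 5 * g$x)
  v <- spatial_average(u, 0.13, g)
  expect_equal(mean(v), mean(u), tolerance = 1e-14)       # mass preserved
  w <- runif(g$n)
  expect_equal(spatial_average(u + 2 * w, 0.13, g),
               spatial_average(u, 0.13, g) + 2 * spatial_average(w, 0.13, g),
               tolerance = 1e-12)                          # linearity

  # single cosine mode is scaled by ~ sinc(kappa * delta), to O(h^2)
  # (the discrete symbol carries an extra sinc(kappa*h/2) cell factor)
  for (m in c(1, 2, 4)) {
    delta <- 0.1
    mode <- cos(2 * pi * m * g$x)
    got <- spatial_average(mode, delta, g)
    expect_lt(max(abs(got - sinc(2 * pi * m * delta) * mode)),
              (pi * m / g$n)^2)
  }

  # a point mass spreads into a plateau of width ~ 2*delta
  pm <- rep(0, g$n)
  pm[40] <- g$n
  sm <- spatial_average(pm, 0.1, g)
  expect_lte(abs(sum(sm > 0.1) - 2 * 0.1 * g$n), 2)
  expect_equal(max(sm), 1 / (2 * 0.1), tolerance = 0.1)

  expect_error(spatial_average(u, 0, g), "delta")
  expect_error(spatial_average(u, 0.5, g), "delta")
})

test_that("taxis flux divergence telescopes and matches the linearised
           prediction for a small cosine mode", {
  g <- spatial_grid(128)
  m <- n2_model(1.7, -0.8, delta = 0.1)
  # homogeneous state and gamma = 0 both give exactly zero
  hom <- population_state(matrix(1, g$n, 2), g)
  expect_true(all(taxis_flux_divergence(hom, m) == 0))
  m0 <- taxis_model(c(1, 1), matrix(0, 2, 2), delta = 0.1)
  st <- random_perturbation_ic(g, 2, amplitude = 0.5, seed = 5)
  expect_true(all(taxis_flux_divergence(st, m0) == 0))
  # conservative form: columns sum to roundoff
  div <- taxis_flux_divergence(st, m)
  expect_lt(max(abs(colSums(div))), 1e-8)

  # linearisation: u1 = 1, u2 = 1 + eps*cos(kx) gives, for population 1,
  # divergence ~ -gamma12 * eps * k^2 * sinc(k*delta) * cos(kx)
  eps <- 1e-6
  mm <- 2
  k <- 2 * pi * mm
  u <- cbind(rep(1, g$n), 1 + eps * cos(k * g$x))
  st2 <- population_state(u, g)
  div2 <- taxis_flux_divergence(st2, m)
  pred <- -m$gamma[1, 2] * eps * k^2 * sinc(k * m$delta) * cos(k * g$x)
  expect_lt(max(abs(div2[, 1] - pred)), 5e-3 * max(abs(pred)))
})

test_that("one compiled step equals the R reference update", {
  g <- spatial_grid(64)
  m <- n2_model(-2, delta = 0.12)
  st <- random_perturbation_ic(g, 2, amplitude = 0.3, seed = 9)
  tau <- 5e-5
  stepped <- step_state(st, m, tau)
  ip1 <- shift_idx(g$n, 1L)
  im1 <- shift_idx(g$n, -1L)
  lap <- (st$u[ip1, ] - 2 * st$u + st$u[im1, ]) / g$h^2
  ref <- st$u + tau * (lap %*% diag(m$d) - taxis_flux_divergence(st, m))
  expect_equal(stepped$u, ref, tolerance = 1e-13)
})

test_that("homogeneous state is an exact fixed point and mass is conserved
           to 1e-12 over 1e5 steps in both schemes", {
  g <- spatial_grid(32)
  m <- n2_model(-2, delta = 0.1)
  hom <- population_state(matrix(1, g$n, 2), g)
  expect_identical(step_state(hom, m, 1e-4)$u, hom$u)
  # the periodic tridiagonal solve leaves ~1 ulp of noise, so the
  # semi-implicit fixed point is exact only to machine precision
  expect_equal(step_state(hom, m, 1e-4, "semi_implicit")$u, hom$u,
               tolerance = 1e-14)

  st <- random_perturbation_ic(g, 2, amplitude = 1e-2, seed = 3)
  for (scheme in c(0L, 1L)) {
    res <- nltaxis:::integrate_chunk(st$u, m, g, tau = 1e-4,
                                     nsteps = 1e5, scheme = scheme)
    expect_lt(max(abs(colMeans(res$u) - 1)), 1e-12)
    expect_gt(min(res$u), 0)
  }
})

test_that("explicit scheme refuses time steps beyond the diffusion
           stability bound and delta = 0 is refused for simulation", {
  m <- n2_model(-2, delta = 0.1)
  expect_error(simulate_model(m, tau = 1e-3, t_end = 1, n = 100),
               "0.4")
  m0 <- n2_model(-2, delta = 0)
  expect_error(simulate_model(m0, tau = 1e-5, t_end = 1, n = 100),
               "ill-posed")
})

test_that("random perturbation ICs are deterministic, mass-exact, and do
           not disturb the caller's RNG", {
  g <- spatial_grid(50)
  a <- random_perturbation_ic(g, 3, amplitude = 1e-3, seed = 21)
  b <- random_perturbation_ic(g, 3, amplitude = 1e-3, seed = 21)
  expect_identical(a$u, b$u)
  expect_equal(colMeans(a$u), rep(1, 3), tolerance = 1e-15)
  expect_gt(min(a$u), 0.99)
  z <- random_perturbation_ic(g, 2, amplitude = 0, seed = 1)
  expect_true(all(z$u == 1))
  expect_error(random_perturbation_ic(g, 2, amplitude = 1, seed = 1),
               "amplitude")
  set.seed(123)
  x1 <- runif(1)
  set.seed(123)
  invisible(random_perturbation_ic(g, 2, seed = 99))
  expect_identical(runif(1), x1)
})

test_that("relabelling populations and cyclic shifts commute with the
           explicit step bit-for-bit", {
  g <- spatial_grid(48)
  m <- n3_template(-4, 1.5, delta = 0.1)
  st <- random_perturbation_ic(g, 3, amplitude = 0.2, seed = 8)
  tau <- 1e-4
  # permutation equivariance
  perm <- c(3L, 1L, 2L)
  mp <- taxis_model(d = rep(1, 3), gamma = m$gamma[perm, perm],
                    delta = m$delta)
  stp <- population_state(st$u[, perm], g)
  expect_identical(step_state(stp, mp, tau)$u,
                   step_state(st, m, tau)$u[, perm])
  # translation equivariance
  sh <- shift_idx(g$n, 13L)
  sts <- population_state(st$u[sh, ], g)
  expect_identical(step_state(sts, m, tau)$u,
                   step_state(st, m, tau)$u[sh, ])
})

test_that("linear-regime growth matches the dispersion relation", {
  # growing segregation mode: eigenvector (1, -1), sigma = k^2(-1 - g*sinc)
  m <- n2_model(-2, delta = 0.1)
  g <- spatial_grid(100)
  k <- 2 * pi
  ic <- cosine_ic(g, 2, m = 1, eps = 1e-6, weights = c(1, -1))
  tr <- simulate_model(m, ic = ic, tau = 1e-5, t_end = 0.02,
                       sample_every = 2e-3)
  rate <- fitted_mode_rate(tr, 1)
  sigma <- k^2 * (-1 - m$gamma[1, 2] * sinc(k * m$delta))
  expect_equal(rate, sigma, tolerance = 0.02 * abs(sigma))
})

test_that("trajectories refine at second order in h", {
  m <- n2_model(-2, delta = 0.125)
  t_end <- 0.05
  final_u <- function(n) {
    g <- spatial_grid(n)
    ic <- cosine_ic(g, 2, m = 1, eps = 0.05, weights = c(1, -1))
    tr <- simulate_model(m, ic = ic, tau = 0.2 / n^2, t_end = t_end,
                         sample_every = t_end)
    state_at(tr)$u
  }
  u64 <- final_u(64)
  u128 <- final_u(128)
  u256 <- final_u(256)
  # compare on the coarse grid (cells of the fine grid average pairwise)
  coarsen <- function(u) (u[seq(1, nrow(u), 2), ] + u[seq(2, nrow(u), 2), ]) / 2
  e1 <- max(abs(coarsen(u128) - u64))
  e2 <- max(abs(coarsen(u256) - u128))
  expect_gt(e1 / e2, 2.5)   # ~4 for O(h^2)
})

test_that("steady-state detection distinguishes settled from growing
           trajectories", {
  m <- n2_model(-2, delta = 0.1)
  hom <- population_state(matrix(1, 32, 2), spatial_grid(32))
  tr <- simulate_model(m, ic = hom, tau = 1e-4, t_end = 0.1,
                       sample_every = 0.02)
  expect_true(steady_state_reached(tr, tol = 1e-8))
  g <- spatial_grid(100)
  ic <- cosine_ic(g, 2, m = 1, eps = 1e-3, weights = c(1, -1))
  tr2 <- simulate_model(m, ic = ic, tau = 1e-5, t_end = 0.05,
                        sample_every = 0.01)
  expect_false(steady_state_reached(tr2, tol = 1e-3))
})
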