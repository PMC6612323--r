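test_that("M(kappa, delta) has the taxis structure with sinc damping", {
  m <- n2_model(-5)
  # kappa*delta -> 0 recovers the local-limit matrix
  expect_equal(build_M(m, kappa = 0), rbind(c(-1, -5), c(-5, -1)))
  expect_equal(build_M(m, kappa = 7, delta = 0),
               rbind(c(-1, -5), c(-5, -1)))
  # sinc zero: off-diagonals vanish at kappa*delta = pi
  M <- build_M(m, kappa = pi / 0.1, delta = 0.1)
  expect_lt(max(abs(M[row(M) != col(M)])), 1e-15)
  # hand value at kappa*delta = pi/2: sinc = 2/pi
  M2 <- build_M(m, kappa = pi / 2 / 0.1, delta = 0.1)
  expect_equal(M2[1, 2], -5 * 2 / pi, tolerance = 1e-12)
  expect_equal(M2[1, 2], -3.1831, tolerance = 1e-4)
})

test_that("sinc is exact at zero and accurate through the series branch", {
  expect_identical(sinc(0), 1)
  x <- c(1e-9, 1e-6, 5e-5, 1e-4, 2e-4, 0.1, pi)
  expect_equal(sinc(x), sin(x) / x, tolerance = 1e-15)
})

test_that("numerical eigenvalues match the two-population closed form", {
  set.seed(42)
  for (rep in 1:200) {
    g12 <- runif(1, -6, 6)
    g21 <- runif(1, -6, 6)
    d2 <- runif(1, 0.2, 4)
    kappa <- runif(1, 0, 60)
    delta <- runif(1, 0.01, 0.45)
    m <- n2_model(g12, g21, d2 = d2, delta = delta)
    sig_num <- kappa^2 *
      sort(Re(eigen(build_M(m, kappa), only.values = TRUE)$values))
    cf <- n2_sigma_closed_form(g12, g21, d2, kappa, delta)
    if (all(Im(cf) == 0)) {
      expect_equal(sig_num, sort(Re(cf)), tolerance = 1e-10)
    } else {
      # complex pair: common real part -(1 + d2)/2 * kappa^2
      ev <- eigen(build_M(m, kappa), only.values = TRUE)$values
      expect_equal(kappa^2 * Re(ev),
                   rep(-(1 + d2) / 2 * kappa^2, 2), tolerance = 1e-8)
    }
  }
})

test_that("dispersion relation: growth vanishes at kappa = 0 and the local
           limit is monotone while finite delta tames it", {
  m <- n2_model(-5, delta = 0.1)
  d <- dispersion_relation(m)
  expect_equal(d$re_sigma[1], 0)
  # finite delta: the unstable band is bounded (positive at small kappa,
  # negative well before the end of the grid)
  expect_gt(max(d$re_sigma), 0)
  expect_lt(d$re_sigma[length(d$kappa)], 0)
  # (the band includes the secondary sinc lobe near kappa*delta ~ 4.5,
  # where 5|sinc| still exceeds 1)
  pos <- d$kappa[d$re_sigma > 0]
  expect_lt(max(pos), 50)

  # local limit with an unstable M0: monotone increasing in kappa
  m0 <- n2_model(-5, delta = 0)
  d0 <- dispersion_relation(m0, kappa = seq(0, 100, length.out = 200))
  expect_true(all(diff(d0$re_sigma) > 0))

  # entrywise continuity of M in delta at fixed kappa
  for (dl in c(1e-2, 1e-4, 1e-6)) {
    expect_equal(build_M(n2_model(-5, delta = dl), kappa = 3),
                 build_M(m0, kappa = 3), tolerance = 20 * dl)
  }
  expect_error(dispersion_relation(m, kappa = numeric(0)), "non-empty")
})

test_that("two-population pattern criterion matches the eigen-sweep in the
           local limit", {
  expect_true(n2_pattern_criterion(-2, -2, 1))
  expect_false(n2_pattern_criterion(2, -2, 1))   # pursue-and-avoid
  expect_false(n2_pattern_criterion(0.5, 0.5, 1))
  expect_error(n2_pattern_criterion(1, 1, 0), "d2")
  set.seed(7)
  for (rep in 1:300) {
    g12 <- runif(1, -4, 4)
    g21 <- runif(1, -4, 4)
    d2 <- runif(1, 0.1, 3)
    if (abs(g12 * g21 - d2) < 1e-8) next
    m <- n2_model(g12, g21, d2 = d2, delta = 0)
    e <- Re(eigen(build_M(m, 0), only.values = TRUE)$values)
    expect_identical(n2_pattern_criterion(g12, g21, d2), max(e) > 0)
  }
})

test_that("two-population patterns are never oscillatory", {
  set.seed(11)
  for (rep in 1:100) {
    m <- n2_model(runif(1, -6, 6), runif(1, -6, 6),
                  d2 = runif(1, 0.2, 3), delta = runif(1, 0.02, 0.3))
    d <- dispersion_relation(m, kappa = seq(0, 80, length.out = 161))
    expect_true(d$regime %in% c("none", "stationary"))
  }
})

test_that("three-population template classifies stationary vs oscillatory
           at the reference parameter points", {
  # stationary pattern point of the regime map
  e <- eigen(build_M(n3_template(-4, -4), kappa = 0),
             only.values = TRUE)$values
  e <- e[order(-Re(e))][1]
  expect_gt(Re(e), 0)
  expect_lt(abs(Im(e)), 1e-8)
  # oscillatory points
  for (g12 in c(4, 3.3)) {
    d <- dispersion_relation(n3_template(g12, -4, delta = 0.1))
    expect_identical(d$regime, "oscillatory")
  }
  # finite-delta stationary case
  d <- dispersion_relation(n3_template(-4, -4, delta = 0.1))
  expect_identical(d$regime, "stationary")
})

test_that("parameter-plane scan reproduces the regime-map corners", {
  tpl <- n3_template(0, 0)
  map <- scan_parameter_plane(tpl, c(1, 2), c(-4, 0, 3.3, 4),
                              c(2, 3), c(-4, 0), delta_mode = "limit")
  get <- function(a, b) map$regimes[match(a, map$grid1), match(b, map$grid2)]
  expect_identical(get(-4, -4), "stationary")
  expect_identical(get(4, -4), "oscillatory")
  expect_identical(get(3.3, -4), "oscillatory")
  expect_identical(get(0, 0), "none")

  # independent oracle for the (0, 0) cell: roots of the characteristic
  # polynomial of M0 via polyroot
  M0 <- build_M(n3_template(0, 0), kappa = 0)
  cp <- c(-det(M0),
          M0[1, 1] * M0[2, 2] - M0[1, 2] * M0[2, 1] +
            M0[1, 1] * M0[3, 3] - M0[1, 3] * M0[3, 1] +
            M0[2, 2] * M0[3, 3] - M0[2, 3] * M0[3, 2],
          -sum(diag(M0)), 1)
  expect_lt(max(Re(polyroot(cp))), 0)

  expect_error(scan_parameter_plane(tpl, c(1, 1), 1:2, c(2, 3), 1:2),
               "diagonal")
  expect_error(scan_parameter_plane(tpl, "gamma[9][1]", 1:2, c(2, 3), 1:2),
               "out of range")
  # string parameter names parse like index pairs
  map2 <- scan_parameter_plane(tpl, "gamma[1][2]", c(-4, 4),
                               "gamma[2][3]", -4, delta_mode = "limit")
  expect_identical(map2$regimes[, 1], c("stationary", "oscillatory"))
})
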