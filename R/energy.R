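# Energy diagnostics for the symmetric two-population system
# (gamma12 = gamma21 = gamma, d = (1, 1)).  The functional
#   E(u1, u2) = int_0^1 { u1 [2 ln u1 - gamma K*u2]
#                       + u2 [2 ln u2 - gamma K*u1] } dx
# decreases monotonically along trajectories and is bounded below by
# -4/e - 2*||K||_inf, with ||K||_inf = 1/(2 delta) for the top-hat kernel,
# so it certifies convergence to a steady state where
# ln(u_i) - gamma K*u_j is spatially constant.

check_symmetric_pair <- function(model) {
  if (model$N != 2L)
    stop("energy diagnostics are defined for exactly 2 populations")
  if (model$gamma[1, 2] != model$gamma[2, 1])
    stop("energy diagnostics require symmetric coupling ",
         "gamma[1,2] == gamma[2,1]")
  if (any(model$d != 1))
    stop("energy diagnostics require d = (1, 1)")
  invisible(model$gamma[1, 2])
}

#' Energy functional of the symmetric two-population system
#'
#' Midpoint-rule quadrature of the energy functional (see the package
#' vignette), using the same discrete top-hat convolution as the solver.
#' For the homogeneous state `E = -2 gamma`; along any trajectory of the
#' symmetric system E is non-increasing and bounded below by
#' `-4/e - 1/delta`.
#'
#' @param u1,u2 strictly positive density vectors on `grid`.
#' @param gamma symmetric taxis coefficient.
#' @param delta averaging half-width in (0, 0.5).
#' @param grid a [spatial_grid()].
#' @return Scalar energy value.
#' @export
energy <- function(u1, u2, gamma, delta, grid) {
  stopifnot(inherits(grid, "spatial_grid"))
  if (any(u1 <= 0) || any(u2 <= 0))
    stop("energy requires strictly positive densities (log undefined)")
  K2 <- spatial_average(u2, delta, grid)
  K1 <- spatial_average(u1, delta, grid)
  grid$h * sum(u1 * (2 * log(u1) - gamma * K2) +
               u2 * (2 * log(u2) - gamma * K1))
}

#' Energy lower bound
#'
#' `-4/e - 2 ||K||_inf` with `||K||_inf = 1/(2 delta)` for the top-hat
#' kernel.
#' @param delta averaging half-width.
#' @return Scalar bound.
#' @export
energy_lower_bound <- function(delta) {
  stopifnot(delta > 0)
  -4 * exp(-1) - 1 / delta
}

#' Audit the energy along a trajectory
#'
#' Evaluates E at every sample of a symmetric two-population trajectory,
#' estimates dE/dt by centred differences, flags any increase beyond a
#' discretisation tolerance, and reports the theoretical lower bound and
#' the closest approach to it.
#'
#' @param traj a `taxis_trajectory` from a symmetric N = 2 model with
#'   `d = (1, 1)` (anything else is an error: the Lyapunov structure is
#'   only established in that case).
#' @param increase_tol per-sample tolerance for an energy increase, as a
#'   fraction of `1 + |E|`.  The default `1e-6 + h^2` absorbs time-stepping
#'   and quadrature noise: the midpoint quadrature and the discrete
#'   convolution are O(h^2) consistent, so the discrete energy is not an
#'   exact Lyapunov function of the discrete scheme and can fluctuate at
#'   that scale during fast transients.
#' @return An object of class `energy_audit`: list with `table`
#'   (data frame `t`, `E`, `dEdt`), `lower_bound`, `min_E`, and
#'   `violations` (data frame of samples where E increased beyond
#'   tolerance; zero rows when the decrease is monotone).
#' @export
energy_audit <- function(traj, increase_tol = NULL) {
  stopifnot(inherits(traj, "taxis_trajectory"))
  if (is.null(increase_tol)) increase_tol <- 1e-6 + traj$grid$h^2
  gamma <- check_symmetric_pair(traj$model)
  delta <- traj$model$delta
  tt <- traj$times
  E <- vapply(traj$states, function(u)
    energy(u[, 1], u[, 2], gamma, delta, traj$grid), numeric(1))
  nt <- length(tt)
  dEdt <- rep(NA_real_, nt)
  if (nt >= 2L) {
    dEdt[1] <- (E[2] - E[1]) / (tt[2] - tt[1])
    dEdt[nt] <- (E[nt] - E[nt - 1]) / (tt[nt] - tt[nt - 1])
    if (nt >= 3L) {
      i <- 2:(nt - 1)
      dEdt[i] <- (E[i + 1] - E[i - 1]) / (tt[i + 1] - tt[i - 1])
    }
  }
  dE <- diff(E)
  tol <- increase_tol * (1 + abs(E[-nt]))
  bad <- which(dE > tol)
  structure(list(table = data.frame(t = tt, E = E, dEdt = dEdt),
                 lower_bound = energy_lower_bound(delta),
                 min_E = min(E),
                 violations = data.frame(t = tt[bad + 1L], dE = dE[bad])),
            class = "energy_audit")
}

#' @export
print.energy_audit <- function(x, ...) {
  n <- nrow(x$table)
  cat("Energy audit over", n, "samples\n")
  cat("  E: ", format(x$table$E[1]), " -> ", format(x$table$E[n]), "\n",
      sep = "")
  cat("  lower bound:", format(x$lower_bound),
      "; closest approach:", format(x$min_E), "\n")
  cat("  increases beyond tolerance:", nrow(x$violations), "\n")
  invisible(x)
}

#' Steady-state residuals of the energy minimum conditions
#'
#' At the energy minimum, `ln(u1) - gamma K*u2` and `ln(u2) - gamma K*u1`
#' are spatially constant (equal to Lagrange-type constants eta1, eta2).
#' This function computes both fields, their spatial means (the eta
#' estimates), and the sup-norm deviation from constancy; the residuals
#' tend to zero as a symmetric run converges.
#'
#' @param state a [population_state()] with two strictly positive columns.
#' @param gamma symmetric taxis coefficient.
#' @param delta averaging half-width.
#' @return An object of class `steady_state_residuals`: list with `eta`
#'   (length 2) and `residual` (length 2, sup-norm deviations).
#' @export
steady_state_residuals <- function(state, gamma, delta) {
  stopifnot(inherits(state, "population_state"), ncol(state$u) == 2L)
  u1 <- state$u[, 1]
  u2 <- state$u[, 2]
  if (any(u1 <= 0) || any(u2 <= 0))
    stop("residuals require strictly positive densities")
  g <- state$grid
  f1 <- log(u1) - gamma * spatial_average(u2, delta, g)
  f2 <- log(u2) - gamma * spatial_average(u1, delta, g)
  eta <- c(mean(f1), mean(f2))
  structure(list(eta = eta,
                 residual = c(max(abs(f1 - eta[1])), max(abs(f2 - eta[2])))),
            class = "steady_state_residuals")
}

#' Aggregation/segregation sign structure of a two-population state
#'
#' At a symmetric steady state, `gamma > 0` forces the gradient of `u1` to
#' share the sign of the gradient of `K*u2` (aggregation) and `gamma < 0`
#' forces opposite signs (segregation).  This classifier compares the two
#' gradients cellwise, ignoring cells where either gradient magnitude is
#' below `tol`, and reports the majority behaviour.
#'
#' @param state a [population_state()] with two columns.
#' @param delta averaging half-width used for the convolution.
#' @param tol gradient magnitude below which a cell is ignored.
#' @return `"aggregation"`, `"segregation"` or `"mixed"` (no cells pass the
#'   threshold, or no majority).
#' @export
sign_structure <- function(state, delta, tol = 1e-6) {
  stopifnot(inherits(state, "population_state"), ncol(state$u) == 2L)
  g <- state$grid
  n <- g$n
  ip1 <- shift_idx(n, 1L)
  im1 <- shift_idx(n, -1L)
  grad <- function(v) (v[ip1] - v[im1]) / (2 * g$h)
  g1 <- grad(state$u[, 1])
  g2 <- grad(spatial_average(state$u[, 2], delta, g))
  use <- abs(g1) >= tol & abs(g2) >= tol
  if (!any(use)) return("mixed")
  frac_same <- mean(sign(g1[use]) == sign(g2[use]))
  if (frac_same > 0.5) "aggregation"
  else if (frac_same < 0.5) "segregation"
  else "mixed"
}

#' Moment-closure curvature at the energy minimum
#'
#' Under the closure `K*u ~ u + sigma2 * u''` (with `sigma2` the kernel
#' variance, `delta^2/3` for the top-hat), the minimum conditions reduce to
#' a scalar relation giving the curvature of the steady profile as a
#' function of the density value:
#' for the aggregation branch (`u1 ~ u2`, `gamma > 0`)
#' \deqn{u'' \approx \{(\ln u - \eta_2)/\gamma - u\}/\sigma^2,}
#' and for the segregation branch (`u1 ~ 2 - u2`, `gamma < 0`)
#' \deqn{u'' \approx \{(\eta_2 + 2\gamma - \ln u)/\gamma - u\}/\sigma^2.}
#' Where the existence condition holds (see [curvature_roots()]), the
#' curvature is positive between two density values `a < b` and negative
#' outside, which is the shape signature of the observed aggregation and
#' segregation profiles.  Both branches are expressed for the population
#' appearing inside the logarithm (`u2`); on the segregation branch the
#' partner profile is its mirror `u1 = 2 - u2`, so its curvature is the
#' negative of the value returned here, with thresholds `2 - b < 2 - a`.
#'
#' @param u density value(s), `> 0`.
#' @param gamma symmetric taxis coefficient, nonzero.
#' @param eta2 steady-state constant from [steady_state_residuals()].
#' @param sigma2 kernel variance (top-hat: `delta^2 / 3`).
#' @param case `"aggregation"` or `"segregation"`.
#' @return Curvature value(s).
#' @export
moment_closure_curvature <- function(u, gamma, eta2, sigma2,
                                     case = c("aggregation", "segregation")) {
  case <- match.arg(case)
  if (gamma == 0) stop("gamma must be nonzero")
  if (any(u <= 0)) stop("u must be > 0")
  if (sigma2 <= 0) stop("sigma2 must be > 0")
  rhs <- if (case == "aggregation") (log(u) - eta2) / gamma - u
         else (eta2 + 2 * gamma - log(u)) / gamma - u
  rhs / sigma2
}

#' Curvature sign-change thresholds
#'
#' Finds the two density values `a < b` where the moment-closure curvature
#' changes sign, when they exist: for the aggregation branch the condition
#' is `eta2 < -1 - log(gamma)` (requires `gamma > 0`), for the segregation
#' branch `eta2 < -1 - log(-gamma) - 2*gamma` (requires `gamma < 0`).
#'
#' @param gamma symmetric taxis coefficient.
#' @param eta2 steady-state constant.
#' @param case `"aggregation"` or `"segregation"`.
#' @return List with `exists` (logical), `a`, `b` (NA when absent) and
#'   `u_extremum` (location of the curvature extremum, `1/|gamma|`).
#' @export
curvature_roots <- function(gamma, eta2,
                            case = c("aggregation", "segregation")) {
  case <- match.arg(case)
  if (case == "aggregation") {
    if (gamma <= 0) stop("aggregation branch requires gamma > 0")
    cond <- eta2 < -1 - log(gamma)
  } else {
    if (gamma >= 0) stop("segregation branch requires gamma < 0")
    cond <- eta2 < -1 - log(-gamma) - 2 * gamma
  }
  u0 <- 1 / abs(gamma)
  if (!cond)
    return(list(exists = FALSE, a = NA_real_, b = NA_real_,
                u_extremum = u0))
  f <- function(u) moment_closure_curvature(u, gamma, eta2, sigma2 = 1,
                                            case = case)
  lo <- u0
  while (f(lo) > 0 && lo > .Machine$double.xmin * 1e10) lo <- lo / 4
  hi <- u0
  while (f(hi) > 0 && hi < 1e12) hi <- hi * 4
  a <- stats::uniroot(f, c(lo, u0), tol = 1e-12)$root
  b <- stats::uniroot(f, c(u0, hi), tol = 1e-12)$root
  list(exists = TRUE, a = a, b = b, u_extremum = u0)
}
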