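#' Periodic spatial grid on the unit interval
#'
#' Cell-centred grid with `n` cells of width `h = 1/n`; centres at
#' `x_k = (k - 1/2) h` under the half-open convention `x` in `[0, 1)`.
#'
#' @param n number of cells, at least 16.
#' @return An object of class `spatial_grid`: list with `n`, `h`, `x`.
#' @export
spatial_grid <- function(n) {
  n <- as.integer(n)
  if (is.na(n) || n < 16L) stop("n must be an integer >= 16")
  structure(list(n = n, h = 1 / n, x = (seq_len(n) - 0.5) / n),
            class = "spatial_grid")
}

# Discrete top-hat weights: weight of cell at offset j is the overlap of
# the window (x - delta, x + delta) with that cell's extent, divided by
# 2*delta.  Cells cut by the window boundary get the partial overlap
# (half weight when the boundary falls on a cell centre), so constants are
# preserved exactly and the operator is O(h^2) consistent with the
# continuous average.
smoothing_weights <- function(delta, grid) {
  if (!is.numeric(delta) || length(delta) != 1L || delta <= 0 || delta >= 0.5)
    stop("delta must lie strictly in (0, 0.5)")
  h <- grid$h
  m <- ceiling(delta / h + 0.5) - 1L
  offsets <- -m:m
  lo <- pmax(-delta, offsets * h - h / 2)
  hi <- pmin(delta, offsets * h + h / 2)
  w <- pmax(hi - lo, 0) / (2 * delta)
  keep <- w > 0
  w <- w[keep] / sum(w[keep])
  list(offsets = offsets[keep], w = w)
}

#' Nonlocal top-hat spatial average
#'
#' Discrete periodic counterpart of
#' \eqn{\bar u(x) = \frac{1}{2\delta}\int_{x-\delta}^{x+\delta} u(z)\,dz}:
#' a circular convolution with exact-overlap top-hat weights.  The operator
#' is linear, returns constants unchanged to machine precision, and
#' preserves the mean (mass) of the field.
#'
#' @param u numeric vector of length `grid$n`, or a matrix with one column
#'   per population.
#' @param delta averaging half-width, strictly in (0, 0.5).
#' @param grid a [spatial_grid()].
#' @return Averaged field, same shape as `u`.
#' @export
spatial_average <- function(u, delta, grid) {
  stopifnot(inherits(grid, "spatial_grid"))
  sw <- smoothing_weights(delta, grid)
  n <- grid$n
  vec <- is.null(dim(u))
  um <- if (vec) matrix(u, ncol = 1L) else u
  if (nrow(um) != n) stop("u must have grid$n rows")
  out <- matrix(0, nrow = n, ncol = ncol(um))
  for (t in seq_along(sw$offsets)) {
    out <- out + sw$w[t] * um[shift_idx(n, sw$offsets[t]), , drop = FALSE]
  }
  if (vec) drop(out) else out
}

#' Population state on a periodic grid
#'
#' @param u matrix of densities, `grid$n` rows by N columns (one column per
#'   population); each column must have discrete mass
#'   `h * sum(u[, i]) == 1` to within `1e-10` and no value below
#'   `-positivity_tol`.
#' @param grid a [spatial_grid()].
#' @param positivity_tol negative excursions beyond this are rejected.
#' @return An object of class `population_state`: list with `u`, `grid`.
#' @export
population_state <- function(u, grid, positivity_tol = 1e-10) {
  stopifnot(inherits(grid, "spatial_grid"))
  u <- as.matrix(u)
  if (nrow(u) != grid$n) stop("u must have grid$n rows")
  mass <- colMeans(u)            # h * colSums(u) since h = 1/n
  if (any(abs(mass - 1) > 1e-10))
    stop("each population must have discrete mass 1 (max deviation ",
         format(max(abs(mass - 1))), ")")
  if (min(u) < -positivity_tol)
    stop("density has negative entries below -positivity_tol")
  structure(list(u = u, grid = grid), class = "population_state")
}

#' Seeded random perturbation of the homogeneous state
#'
#' Each density is `1 + amplitude * xi` with `xi` i.i.d. uniform on
#' `[-1, 1]` per cell, recentred and rescaled per population so the
#' discrete mass is exactly 1.  Deterministic given `seed`; the caller's
#' RNG state is left untouched.
#'
#' @param grid a [spatial_grid()].
#' @param N number of populations.
#' @param amplitude perturbation amplitude in `[0, 1)`; amplitudes `>= 1`
#'   are rejected because they risk negative densities.
#' @param seed integer seed, or NULL to use the current RNG state.
#' @return A [population_state()].
#' @export
random_perturbation_ic <- function(grid, N, amplitude = 1e-3, seed = NULL) {
  stopifnot(inherits(grid, "spatial_grid"), N >= 1)
  if (!is.numeric(amplitude) || amplitude < 0)
    stop("amplitude must be >= 0")
  if (amplitude >= 1)
    stop("amplitude must be < 1 to keep densities positive")
  xi <- with_seed(seed, matrix(runif(grid$n * N, -1, 1), grid$n, N))
  u <- 1 + amplitude * sweep(xi, 2L, colMeans(xi))
  u <- sweep(u, 2L, colMeans(u), "/")
  population_state(u, grid)
}

#' Taxis flux divergence (conservative form)
#'
#' Computes \eqn{\partial/\partial x (u_i \sum_j \gamma_{ij}
#' \partial\bar u_j/\partial x)} for every population, using the same
#' discretisation as the time stepper: velocities from centred face
#' differences of the averaged fields, face densities by arithmetic mean,
#' divergence as the face-flux difference over `h`.  The flux telescopes
#' around the ring, so each column sums to zero up to roundoff.
#'
#' @param state a [population_state()].
#' @param model a [taxis_model()] with `delta > 0`.
#' @return Matrix of the same shape as `state$u`.
#' @export
taxis_flux_divergence <- function(state, model) {
  stopifnot(inherits(state, "population_state"),
            inherits(model, "taxis_model"))
  if (ncol(state$u) != model$N)
    stop("state has ", ncol(state$u), " populations but model has ", model$N)
  g <- state$grid
  n <- g$n
  h <- g$h
  ub <- spatial_average(state$u, model$delta, g)
  ip1 <- shift_idx(n, 1L)
  im1 <- shift_idx(n, -1L)
  dub_face <- (ub[ip1, , drop = FALSE] - ub) / h
  div <- matrix(0, n, model$N)
  for (i in seq_len(model$N)) {
    V <- as.vector(dub_face %*% model$gamma[i, ])
    uf <- 0.5 * (state$u[, i] + state$u[ip1, i])
    FF <- uf * V
    div[, i] <- (FF - FF[im1]) / h
  }
  div
}

# Shared validation + dispatch into the compiled stepper.
integrate_chunk <- function(u, model, grid, tau, nsteps, scheme,
                            positivity_tol = 1e-10) {
  sw <- smoothing_weights(model$delta, grid)
  wm <- max(sw$offsets)
  w <- numeric(2L * wm + 1L)
  w[sw$offsets + wm + 1L] <- sw$w
  res <- cpp_integrate(u, model$d, model$gamma, w, wm, tau, grid$h,
                       as.integer(nsteps), as.integer(scheme),
                       positivity_tol)
  if (res$status != 0L)
    stop("integration failed: density fell below -positivity_tol at step ",
         res$fail_step, " (of ", nsteps, " in this chunk); reduce tau",
         call. = FALSE)
  res
}

check_scheme <- function(model, grid, tau, scheme) {
  if (model$delta <= 0)
    stop("simulation requires delta > 0: the local limit delta = 0 is ",
         "ill-posed (unstable at arbitrarily high wavenumbers)")
  if (scheme == "explicit") {
    cfl <- 0.4 * grid$h^2 / max(model$d)
    if (tau > cfl)
      stop("explicit scheme requires tau <= 0.4*h^2/max(d) = ",
           format(cfl), " (diffusion stability with safety margin); ",
           "got tau = ", format(tau))
  }
  invisible(TRUE)
}

#' Advance a population state by one time step
#'
#' Single step of the conservative scheme: explicit Euler (centred
#' diffusion plus taxis flux divergence), or the semi-implicit variant with
#' backward-Euler diffusion and explicit taxis.  Discrete mass is conserved
#' exactly (telescoping fluxes) and the homogeneous state is an exact fixed
#' point of the explicit scheme.
#'
#' @param state a [population_state()].
#' @param model a [taxis_model()] with `delta > 0`.
#' @param tau time step.  The explicit scheme refuses
#'   `tau > 0.4 h^2 / max(d)`.
#' @param scheme `"explicit"` or `"semi_implicit"`.
#' @return The updated [population_state()].
#' @export
step_state <- function(state, model, tau,
                       scheme = c("explicit", "semi_implicit")) {
  stopifnot(inherits(state, "population_state"),
            inherits(model, "taxis_model"), tau > 0)
  scheme <- match.arg(scheme)
  check_scheme(model, state$grid, tau, scheme)
  res <- integrate_chunk(state$u, model, state$grid, tau, 1L,
                         if (scheme == "explicit") 0L else 1L)
  out <- state
  out$u <- res$u
  out
}

#' Integrate the nonlocal diffusion-taxis system
#'
#' Runs the conservative finite-difference scheme from a given (or randomly
#' perturbed) initial condition, sampling the state every `sample_every`
#' time units and recording per-sample conservation and positivity
#' diagnostics.
#'
#' @param model a [taxis_model()] with `delta > 0` (the local limit is
#'   refused as ill-posed).
#' @param ic a [population_state()], or NULL to start from
#'   [random_perturbation_ic()] with the given `n`, `amplitude`, `seed`.
#' @param tau time step (default the reference resolution `1e-5`).
#' @param t_end final time.
#' @param sample_every sampling interval; rounded to a whole number of
#'   steps.
#' @param n grid cells when `ic` is NULL.
#' @param amplitude,seed initial-condition parameters when `ic` is NULL.
#' @param scheme `"explicit"` (default) or `"semi_implicit"` (implicit
#'   diffusion, explicit taxis; stable at larger `tau` for long sweeps).
#' @param stop_when_steady if TRUE, stop early once
#'   [steady_state_reached()] holds with tolerance `steady_tol` over the
#'   last two samples.
#' @param steady_tol sup-norm change per unit time below which the run is
#'   declared steady.
#' @return An object of class `taxis_trajectory`: list with `times`,
#'   `states` (list of density matrices), `diagnostics` (long data frame:
#'   `t`, `population`, `mass_error`, `min_u`, `max_u`), `model`, `tau`,
#'   `scheme`, and `status` (`"completed"` or `"steady"`).
#' @export
#' @examples
#' m <- taxis_model(d = c(1, 1), gamma = rbind(c(0, -2), c(-2, 0)),
#'                  delta = 0.1)
#' tr <- simulate_model(m, t_end = 0.02, tau = 2e-5, n = 50,
#'                      sample_every = 0.01, seed = 1)
#' tail(tr$diagnostics, 2)
simulate_model <- function(model, ic = NULL, tau = 1e-5, t_end = 10,
                           sample_every = 0.01, n = 100, amplitude = 1e-3,
                           seed = NULL,
                           scheme = c("explicit", "semi_implicit"),
                           stop_when_steady = FALSE, steady_tol = 1e-3) {
  stopifnot(inherits(model, "taxis_model"), tau > 0, t_end > 0)
  scheme <- match.arg(scheme)
  if (is.null(ic)) {
    ic <- random_perturbation_ic(spatial_grid(n), model$N,
                                 amplitude = amplitude, seed = seed)
  }
  stopifnot(inherits(ic, "population_state"))
  if (ncol(ic$u) != model$N)
    stop("initial condition has ", ncol(ic$u), " populations, model has ",
         model$N)
  grid <- ic$grid
  check_scheme(model, grid, tau, scheme)
  steps_per_sample <- max(1L, as.integer(round(sample_every / tau)))
  dt_sample <- steps_per_sample * tau
  nsamples <- ceiling(t_end / dt_sample)
  scheme_code <- if (scheme == "explicit") 0L else 1L

  u <- ic$u
  mass0 <- colMeans(u)
  times <- numeric(nsamples + 1L)
  states <- vector("list", nsamples + 1L)
  diag_rows <- vector("list", nsamples + 1L)
  snap <- function(s, t, u) {
    times[s] <<- t
    states[[s]] <<- u
    diag_rows[[s]] <<- data.frame(
      t = t, population = seq_len(model$N),
      mass_error = abs(colMeans(u) - mass0) / mass0,
      min_u = apply(u, 2L, min), max_u = apply(u, 2L, max))
  }
  snap(1L, 0, u)
  status <- "completed"
  last <- 1L
  for (s in seq_len(nsamples)) {
    res <- tryCatch(
      integrate_chunk(u, model, grid, tau, steps_per_sample, scheme_code),
      error = function(e) {
        stop("at t ~ ", format((s - 1L) * dt_sample), ": ",
             conditionMessage(e), call. = FALSE)
      })
    u <- res$u
    last <- s + 1L
    snap(last, s * dt_sample, u)
    if (stop_when_steady && s >= 2L) {
      dchange <- max(abs(states[[last]] - states[[last - 1L]])) / dt_sample
      if (dchange < steady_tol) {
        status <- "steady"
        break
      }
    }
  }
  structure(list(times = times[seq_len(last)],
                 states = states[seq_len(last)],
                 diagnostics = do.call(rbind, diag_rows[seq_len(last)]),
                 model = model, grid = grid, tau = tau, scheme = scheme,
                 sample_every = dt_sample, status = status),
            class = "taxis_trajectory")
}

#' @export
print.taxis_trajectory <- function(x, ...) {
  cat("Taxis trajectory:", length(x$times), "samples on [",
      format(x$times[1]), ",", format(x$times[length(x$times)]), "]\n")
  cat("  grid n =", x$grid$n, ", tau =", format(x$tau),
      ", scheme =", x$scheme, ", status =", x$status, "\n")
  cat("  max |mass error| =", format(max(x$diagnostics$mass_error)), "\n")
  invisible(x)
}

#' Test whether a trajectory has reached a steady state
#'
#' TRUE when the sup-norm change per unit time between consecutive samples
#' stays below `tol` over the tail window of the trajectory.
#'
#' @param traj a `taxis_trajectory`.
#' @param tol threshold on sup-norm change per unit time.
#' @param window length of the tail window in time units; default spans the
#'   last two samples.
#' @return logical.
#' @export
steady_state_reached <- function(traj, tol = 1e-3, window = NULL) {
  stopifnot(inherits(traj, "taxis_trajectory"))
  nt <- length(traj$times)
  if (nt < 2L) stop("need at least 2 samples to assess steadiness")
  t_end <- traj$times[nt]
  if (is.null(window)) window <- t_end - traj$times[nt - 1L]
  sel <- which(traj$times >= t_end - window - 1e-12)
  if (length(sel) < 2L) sel <- c(nt - 1L, nt)
  rate <- vapply(seq_along(sel)[-1L], function(k) {
    i <- sel[k]
    j <- sel[k - 1L]
    max(abs(traj$states[[i]] - traj$states[[j]])) /
      (traj$times[i] - traj$times[j])
  }, numeric(1))
  all(rate < tol)
}

# Wrap a density matrix as a population_state without revalidation (for
# states produced by the integrator itself, whose mass is conserved up to
# roundoff).
as_population_state <- function(u, grid) {
  structure(list(u = u, grid = grid), class = "population_state")
}

#' State at a sampled time of a trajectory
#'
#' @param traj a `taxis_trajectory`.
#' @param t time of the requested sample (nearest sample is used); NULL for
#'   the final state.
#' @return A [population_state()].
#' @export
state_at <- function(traj, t = NULL) {
  i <- if (is.null(t)) length(traj$times) else which.min(abs(traj$times - t))
  as_population_state(traj$states[[i]], traj$grid)
}
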