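#' Non-dimensional diffusion-taxis model
#'
#' Defines the non-dimensional model for N populations on the periodic unit
#' interval,
#' \deqn{\partial u_i/\partial t = d_i \partial^2 u_i/\partial x^2 -
#'   \partial/\partial x\bigl(u_i \sum_{j \ne i} \gamma_{ij}
#'   \partial \bar u_j/\partial x\bigr),}
#' where \eqn{\bar u_j} is the top-hat average of \eqn{u_j} over a window of
#' half-width `delta`.  Each density integrates to 1, so the homogeneous
#' steady state is \eqn{u_i \equiv 1}.
#'
#' @param d numeric vector of relative diffusivities \eqn{d_i = D_i/D_1};
#'   `d[1]` must be exactly 1 and all entries positive.
#' @param gamma N x N matrix of dimensionless taxis coefficients
#'   \eqn{\gamma_{ij}}; `gamma[i, j] > 0` means population i moves towards
#'   population j, `< 0` away from it.  The diagonal must be exactly zero:
#'   self-interaction is deliberately outside the framework, so nonzero
#'   diagonal entries are an error rather than being silently dropped.
#' @param delta half-width of the spatial averaging window, in units of the
#'   domain length; must satisfy `0 <= delta <= 0.5` so the window never
#'   wraps onto itself.  The endpoints are allowed for linear analysis
#'   only: simulation refuses `delta = 0` (the local limit is ill-posed)
#'   and requires `delta < 0.5`.
#' @param kernel averaging kernel; only `"top_hat"` (uniform on
#'   `(-delta, delta)`) is implemented.
#'
#' @return An object of class `taxis_model`: a list with elements `N`, `d`,
#'   `gamma`, `delta`, `kernel`.
#' @seealso [nondimensionalize()] to build a model from dimensional scenario
#'   parameters, [dispersion_relation()], [simulate_model()].
#' @export
#' @examples
#' m <- taxis_model(d = c(1, 1), gamma = rbind(c(0, -2), c(-2, 0)),
#'                  delta = 0.1)
#' classify_pair(m$gamma[1, 2], m$gamma[2, 1])
taxis_model <- function(d, gamma, delta, kernel = "top_hat") {
  d <- as.numeric(d)
  N <- length(d)
  if (N < 2L)
    stop("a taxis model needs at least 2 populations (length(d) >= 2)")
  if (d[1] != 1)
    stop("d[1] must be exactly 1: diffusivities are relative to population 1")
  if (any(d <= 0)) stop("all relative diffusivities d must be positive")
  gamma <- as.matrix(gamma)
  if (!is.numeric(gamma) || nrow(gamma) != N || ncol(gamma) != N)
    stop("gamma must be a numeric ", N, " x ", N, " matrix")
  if (any(diag(gamma) != 0))
    stop("diagonal entries of gamma must be zero: self-interaction ",
         "(gamma[i,i] != 0) is not part of this framework")
  if (!is.numeric(delta) || length(delta) != 1L || is.na(delta) ||
      delta < 0 || delta > 0.5)
    stop("delta must be a single value in [0, 0.5]")
  kernel <- match.arg(kernel, "top_hat")
  structure(list(N = N, d = d, gamma = unname(gamma), delta = delta,
                 kernel = kernel),
            class = "taxis_model")
}

#' @export
print.taxis_model <- function(x, ...) {
  cat("Nonlocal diffusion-taxis model\n")
  cat("  populations:", x$N, "\n")
  cat("  d:          ", paste(signif(x$d, 6), collapse = ", "), "\n")
  cat("  delta:      ", x$delta, " (", x$kernel, " kernel)\n", sep = "")
  cat("  gamma:\n")
  print(x$gamma)
  invisible(x)
}

#' Dimensional parameters for the three interaction scenarios
#'
#' Collects the dimensional parameters of one of the three mechanistic
#' scenarios by which populations sense each other: direct sensing of the
#' (locally averaged) foreign density (scenario 1), scent marks deposited at
#' rate `A[i, j]` and decaying at rate `mu` (scenario 2, stigmergy), or a
#' shared cognitive map of past encounters discounted at rate `nu`
#' (scenario 3, spatial memory).  The mark and memory fields are assumed to
#' equilibrate fast relative to the densities, with no memory decay
#' (`zeta = 0`); only this quasi-equilibrium limit enters the model, so the
#' mark/memory fields themselves never appear at runtime.
#'
#' @param scenario 1, 2 or 3.
#' @param L domain length (length units).
#' @param D vector of diffusion magnitudes \eqn{D_i} (length^2/time), all
#'   positive.
#' @param c vector of taxis magnitudes \eqn{c_i \ge 0}.
#' @param A N x N coefficient matrix: \eqn{a_{ij}} (scenario 1),
#'   \eqn{\alpha_{ij}} (scenario 2) or \eqn{\beta_{ij}} (scenario 3).  The
#'   diagonal is ignored.
#' @param mu mark decay rate, required positive for scenario 2.
#' @param nu memory discount rate, required positive for scenario 3.
#' @param zeta memory decay rate; must be 0, since the quasi-equilibrium
#'   reduction used throughout is only valid without memory decay.  A
#'   positive value is rejected rather than silently ignored.
#' @return An object of class `scenario_params`.
#' @seealso [nondimensionalize()]
#' @export
scenario_params <- function(scenario, L, D, c, A, mu = NULL, nu = NULL,
                            zeta = 0) {
  if (!scenario %in% 1:3) stop("scenario must be 1, 2 or 3")
  if (!is.numeric(L) || length(L) != 1L || L <= 0) stop("L must be > 0")
  D <- as.numeric(D)
  N <- length(D)
  if (N < 2L) stop("need at least 2 populations")
  if (D[1] <= 0) stop("D[1] must be > 0")
  if (any(D <= 0)) stop("all diffusion magnitudes D must be > 0")
  c <- as.numeric(c)
  if (length(c) != N || any(c < 0)) stop("c must be length ", N, " with c >= 0")
  A <- as.matrix(A)
  if (nrow(A) != N || ncol(A) != N)
    stop("A must be a ", N, " x ", N, " matrix")
  if (scenario == 2 && (is.null(mu) || mu <= 0))
    stop("scenario 2 requires a mark decay rate mu > 0")
  if (scenario == 3 && (is.null(nu) || nu <= 0))
    stop("scenario 3 requires a memory discount rate nu > 0")
  if (zeta != 0)
    stop("zeta must be 0: the fast-equilibration reduction assumes ",
         "no memory decay")
  structure(list(scenario = scenario, L = L, D = D, c = c, A = unname(A),
                 mu = mu, nu = nu, zeta = 0, N = N),
            class = "scenario_params")
}

#' Map dimensional scenario parameters onto the non-dimensional model
#'
#' Applies the non-dimensionalisation \eqn{d_i = D_i/D_1} and
#' \deqn{\gamma_{ij} = c_i a_{ij}/(L D_1) \quad\text{(scenario 1)},\qquad
#'   c_i \alpha_{ij}/(\mu L D_1) \quad\text{(2)},\qquad
#'   c_i \beta_{ij}/(\nu L D_1) \quad\text{(3)}.}
#' The diagonal of the resulting `gamma` is forced to zero, and the
#' averaging half-width `delta` (already in units of the domain length) is
#' passed through unchanged.
#'
#' @param params a [scenario_params()] object.
#' @param delta dimensionless averaging half-width for the resulting model.
#' @return A [taxis_model()].
#' @export
#' @examples
#' p <- scenario_params(2, L = 2, D = c(1, 2), c = c(3, 1),
#'                      A = rbind(c(0, 4), c(-2, 0)), mu = 2)
#' nondimensionalize(p, delta = 0.1)$gamma  # gamma12 = 3, gamma21 = -0.5
nondimensionalize <- function(params, delta = 0.1) {
  stopifnot(inherits(params, "scenario_params"))
  rate <- switch(params$scenario, `1` = 1, `2` = params$mu, `3` = params$nu)
  gamma <- (params$c / (rate * params$L * params$D[1])) * params$A
  diag(gamma) <- 0
  taxis_model(d = params$D / params$D[1], gamma = gamma, delta = delta)
}

#' Classify a pairwise interaction
#'
#' The sign pattern of \eqn{(\gamma_{ij}, \gamma_{ji})} determines the
#' biological character of the interaction between populations i and j:
#' both positive is mutual attraction, both negative mutual avoidance, and
#' strictly opposite signs is "pursue-and-avoid" (i chases j while j flees,
#' or vice versa).  A zero coefficient in either direction is an edge case
#' outside the three-way taxonomy.
#'
#' @param gamma_ij,gamma_ji the two directed taxis coefficients.
#' @return One of `"mutual_attraction"`, `"mutual_avoidance"`,
#'   `"pursue_and_avoid"`, `"edge_case"`.
#' @export
classify_pair <- function(gamma_ij, gamma_ji) {
  stopifnot(is.numeric(gamma_ij), is.numeric(gamma_ji),
            length(gamma_ij) == 1L, length(gamma_ji) == 1L)
  if (gamma_ij == 0 || gamma_ji == 0) return("edge_case")
  if (gamma_ij > 0 && gamma_ji > 0) return("mutual_attraction")
  if (gamma_ij < 0 && gamma_ji < 0) return("mutual_avoidance")
  "pursue_and_avoid"
}

#' Interaction digraph of a model
#'
#' Emits one directed edge per ordered pair (i, j), i != j, with
#' `gamma[i, j] != 0`, labelled by the sign of the coefficient.  This is the
#' machine-readable form of the schematic diagrams used to summarise
#' interaction structure: an arrow from i towards j for attraction
#' (`sign = +1`), an arrow from i pointing away from j for avoidance
#' (`sign = -1`).
#'
#' @param model a [taxis_model()].
#' @return A data frame with integer columns `from`, `to`, `sign`.
#' @export
interaction_digraph <- function(model) {
  stopifnot(inherits(model, "taxis_model"))
  idx <- which(model$gamma != 0, arr.ind = TRUE)
  idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
  data.frame(from = as.integer(idx[, 1]),
             to = as.integer(idx[, 2]),
             sign = as.integer(sign(model$gamma[idx])))
}
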