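#' Cardinal sine
#'
#' `sinc(x) = sin(x)/x`, with a series branch near zero so that
#' `sinc(0) == 1` exactly and no 0/0 occurs.
#'
#' @param x numeric vector.
#' @return numeric vector of the same length.
#' @export
sinc <- function(x) {
  x <- as.numeric(x)
  out <- numeric(length(x))
  big <- abs(x) >= 1e-4
  out[big] <- sin(x[big]) / x[big]
  s <- x[!big]
  out[!big] <- 1 - s^2 / 6 + s^4 / 120
  out
}

#' Linearisation matrix M(kappa, delta)
#'
#' The growth rate sigma of a perturbation mode with wavenumber kappa about
#' the homogeneous state satisfies \eqn{\sigma w = \kappa^2 M(\kappa,\delta)
#' w}, where M has diagonal \eqn{-d_i} and off-diagonal entries
#' \eqn{\gamma_{ij}\,\mathrm{sinc}(\kappa\delta)}.  With `kappa * delta = 0`
#' the sinc factor is exactly 1 and M reduces to the kappa-independent local
#' limit M0.
#'
#' @param model a [taxis_model()].
#' @param kappa wavenumber, `>= 0`.
#' @param delta averaging half-width; defaults to the model's.
#' @return An N x N numeric matrix.
#' @export
build_M <- function(model, kappa, delta = model$delta) {
  stopifnot(inherits(model, "taxis_model"), kappa >= 0, delta >= 0)
  M <- model$gamma * sinc(kappa * delta)
  diag(M) <- -model$d
  M
}

# Dominant eigenvalue: largest real part, ties broken by larger |imaginary
# part| so that oscillatory detection is conservative and deterministic.
dominant_eigen <- function(M) {
  ev <- eigen(M, only.values = TRUE)$values
  ev <- as.complex(ev)
  ev[order(-Re(ev), -abs(Im(ev)))][1]
}

#' Dispersion relation over a wavenumber grid
#'
#' For each wavenumber in `kappa`, computes the eigenvalues of
#' \eqn{\kappa^2 M(\kappa, \delta)} and records the dominant one (largest
#' real part; ties broken by larger absolute imaginary part).  Patterns form
#' when the dominant growth rate is positive for some kappa; the pattern is
#' stationary (Turing-type) when that eigenvalue is real and oscillatory
#' (wave instability) when it is complex.
#'
#' @param model a [taxis_model()].
#' @param kappa nonnegative, sorted wavenumber grid.  The default covers
#'   `[0, 100]` with 400 points.
#' @param tol_re threshold on the maximal growth rate below which the regime
#'   is `"none"`; defaults to `1e-9 * max(kappa)^2`, i.e. a fixed tolerance
#'   on the eigenvalues of M itself.
#' @param tol_im threshold on `|Im sigma|` separating stationary from
#'   oscillatory at the most unstable wavenumber.
#' @return An object of class `dispersion_result`: list with `kappa`,
#'   `re_sigma`, `im_sigma`, `kappa_star` (most unstable wavenumber) and
#'   `regime` (`"none"`, `"stationary"` or `"oscillatory"`).
#' @export
#' @examples
#' m <- taxis_model(d = c(1, 1), gamma = rbind(c(0, -5), c(-5, 0)),
#'                  delta = 0.1)
#' d <- dispersion_relation(m)
#' d$regime
#' d$kappa_star
dispersion_relation <- function(model,
                                kappa = seq(0, 100, length.out = 400),
                                tol_re = NULL, tol_im = 1e-8) {
  stopifnot(inherits(model, "taxis_model"))
  if (length(kappa) == 0L) stop("kappa grid must be non-empty")
  if (any(kappa < 0)) stop("kappa grid must be nonnegative")
  if (is.unsorted(kappa)) stop("kappa grid must be sorted increasing")
  if (is.null(tol_re)) tol_re <- 1e-9 * max(kappa)^2
  sig <- vapply(kappa, function(k) {
    k^2 * dominant_eigen(build_M(model, k))
  }, complex(1))
  re_sigma <- Re(sig)
  im_sigma <- Im(sig)
  structure(list(kappa = kappa, re_sigma = re_sigma, im_sigma = im_sigma,
                 kappa_star = kappa[which.max(re_sigma)],
                 regime = classify_regime(re_sigma, im_sigma,
                                          tol_re = tol_re, tol_im = tol_im),
                 model = model),
            class = "dispersion_result")
}

#' @export
as.data.frame.dispersion_result <- function(x, ...) {
  data.frame(kappa = x$kappa, re_sigma = x$re_sigma, im_sigma = x$im_sigma)
}

#' @export
print.dispersion_result <- function(x, ...) {
  cat("Dispersion relation over", length(x$kappa), "wavenumbers\n")
  cat("  regime:     ", x$regime, "\n")
  cat("  max Re sigma:", signif(max(x$re_sigma), 6),
      "at kappa* =", signif(x$kappa_star, 6), "\n")
  invisible(x)
}

#' Classify the linear regime of an eigenvalue sweep
#'
#' `"none"` if the maximal real part does not exceed `tol_re`; otherwise
#' `"stationary"` if the dominant eigenvalue at the maximising wavenumber is
#' real to within `tol_im`, else `"oscillatory"`.
#'
#' @param re_sigma,im_sigma real and imaginary parts of the dominant
#'   eigenvalue along the sweep (any positive length; a single pair
#'   classifies the kappa-independent local limit).
#' @param tol_re,tol_im classification tolerances.
#' @return `"none"`, `"stationary"` or `"oscillatory"`.
#' @export
classify_regime <- function(re_sigma, im_sigma, tol_re = 1e-9,
                            tol_im = 1e-8) {
  stopifnot(length(re_sigma) == length(im_sigma), length(re_sigma) >= 1L)
  i <- which.max(re_sigma)
  if (re_sigma[i] <= tol_re) return("none")
  if (abs(im_sigma[i]) <= tol_im) "stationary" else "oscillatory"
}

#' Two-population pattern-formation criterion
#'
#' For N = 2 the dominant eigenvalue is positive for some wavenumber if and
#' only if \eqn{\gamma_{12}\gamma_{21} > d_2} (necessary for any
#' `delta`; also sufficient in the local limit `delta -> 0`).  In
#' particular pursue-and-avoid interactions (opposite signs, negative
#' product) can never form patterns.
#'
#' @param gamma12,gamma21 taxis coefficients.
#' @param d2 relative diffusivity of population 2, `> 0`.
#' @return logical.
#' @export
n2_pattern_criterion <- function(gamma12, gamma21, d2) {
  if (!is.numeric(d2) || any(d2 <= 0)) stop("d2 must be > 0")
  gamma12 * gamma21 > d2
}

#' Closed-form two-population eigenvalues
#'
#' The growth rates for N = 2 in closed form:
#' \deqn{\sigma_\pm(\kappa) = \frac{\kappa^2}{2}\Bigl[-(1+d_2) \pm
#'   \sqrt{(1+d_2)^2 + 4(\gamma_{12}\gamma_{21}
#'   \mathrm{sinc}^2(\kappa\delta) - d_2)}\Bigr].}
#' Complex values (negative discriminant) are returned as complex numbers;
#' their common real part \eqn{-\kappa^2(1+d_2)/2} is always negative, which
#' is why two-population patterns are never oscillatory.
#'
#' @param gamma12,gamma21 taxis coefficients.
#' @param d2 relative diffusivity of population 2.
#' @param kappa wavenumber vector.
#' @param delta averaging half-width.
#' @return A complex matrix with columns `sigma_plus`, `sigma_minus`
#'   (rows follow `kappa`).
#' @export
n2_sigma_closed_form <- function(gamma12, gamma21, d2, kappa, delta) {
  s <- sinc(kappa * delta)
  disc <- as.complex((1 + d2)^2 + 4 * (gamma12 * gamma21 * s^2 - d2))
  root <- sqrt(disc)
  cbind(sigma_plus = kappa^2 * (-(1 + d2) + root) / 2,
        sigma_minus = kappa^2 * (-(1 + d2) - root) / 2)
}

# Accept a gamma-entry spec either as an integer pair c(i, j) or as a
# string "gamma[i][j]".
parse_gamma_param <- function(p, N) {
  if (is.character(p)) {
    m <- regmatches(p, regexec("^gamma\\[(\\d+)\\]\\[(\\d+)\\]$", p))[[1]]
    if (length(m) != 3L)
      stop("cannot parse parameter name '", p,
           "'; expected \"gamma[i][j]\" or an index pair c(i, j)")
    p <- as.integer(m[2:3])
  }
  p <- as.integer(p)
  if (length(p) != 2L || any(is.na(p)) || any(p < 1L) || any(p > N))
    stop("gamma index pair out of range for N = ", N)
  if (p[1] == p[2])
    stop("cannot scan a diagonal gamma entry (self-interaction is excluded)")
  p
}

#' Scan a two-parameter plane for linear pattern-formation regimes
#'
#' Varies two entries of the taxis matrix over grids and classifies the
#' linear regime at each grid point.  In the default `"limit"` mode the
#' spectrum of the local-limit matrix M0 is used (the eigenvalues of
#' \eqn{\kappa^2 M_0} scale with \eqn{\kappa^2}, so the classification is
#' kappa-independent); in `"finite"` mode a full dispersion sweep at the
#' model's `delta` is performed per cell.
#'
#' @param template a [taxis_model()] providing all fixed parameters.
#' @param param1,param2 entries of gamma to vary: index pairs `c(i, j)` or
#'   strings `"gamma[i][j]"`.
#' @param grid1,grid2 numeric value grids for the two parameters.
#' @param delta_mode `"limit"` (local limit, M0 spectrum) or `"finite"`.
#' @param kappa wavenumber grid for `"finite"` mode.
#' @param tol_re,tol_im classification tolerances, see [classify_regime()].
#' @return An object of class `regime_map`: list with `param1`, `param2`
#'   (index pairs), `grid1`, `grid2`, `regimes` (character matrix,
#'   `length(grid1)` rows by `length(grid2)` columns) and `delta_mode`.
#' @export
scan_parameter_plane <- function(template, param1, grid1, param2, grid2,
                                 delta_mode = c("limit", "finite"),
                                 kappa = seq(0, 100, length.out = 400),
                                 tol_re = 1e-9, tol_im = 1e-8) {
  stopifnot(inherits(template, "taxis_model"))
  delta_mode <- match.arg(delta_mode)
  p1 <- parse_gamma_param(param1, template$N)
  p2 <- parse_gamma_param(param2, template$N)
  if (!is.numeric(grid1) || !is.numeric(grid2) ||
      !length(grid1) || !length(grid2) ||
      any(!is.finite(grid1)) || any(!is.finite(grid2)))
    stop("parameter grids must be finite numeric vectors")
  regimes <- matrix(NA_character_, length(grid1), length(grid2))
  for (a in seq_along(grid1)) {
    for (b in seq_along(grid2)) {
      m <- template
      m$gamma[p1[1], p1[2]] <- grid1[a]
      m$gamma[p2[1], p2[2]] <- grid2[b]
      if (delta_mode == "limit") {
        e <- dominant_eigen(build_M(m, kappa = 0))
        regimes[a, b] <- classify_regime(Re(e), Im(e),
                                         tol_re = tol_re, tol_im = tol_im)
      } else {
        regimes[a, b] <- dispersion_relation(m, kappa = kappa,
                                             tol_im = tol_im)$regime
      }
    }
  }
  structure(list(param1 = p1, param2 = p2, grid1 = grid1, grid2 = grid2,
                 regimes = regimes, delta_mode = delta_mode),
            class = "regime_map")
}

#' @export
print.regime_map <- function(x, ...) {
  cat(sprintf("Regime map: gamma[%d][%d] (%d values) x gamma[%d][%d] (%d values), %s mode\n",
              x$param1[1], x$param1[2], length(x$grid1),
              x$param2[1], x$param2[2], length(x$grid2), x$delta_mode))
  print(table(x$regimes))
  invisible(x)
}
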