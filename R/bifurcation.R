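# Quasi-continuation bifurcation analysis: sweep a taxis coefficient in
# small increments, warm-starting each stage from the previous final state,
# record the orbit of the densities at a probe point, and classify its
# period by peak-height matching.  Against the three-population template
# this localises the period-doubling cascade of the oscillatory patterns.

#' Extract a probe-point time series from a trajectory
#'
#' Returns the sampled values of every population at the cell centre
#' nearest `x_probe` (ties broken towards the lower index), restricted to a
#' time window.
#'
#' @param traj a `taxis_trajectory`.
#' @param x_probe probe location in `[0, 1)`.
#' @param window `c(t0, t1)` time window; default the full span.
#' @return A data frame with column `t` and one column `u1`, `u2`, ... per
#'   population; attributes `probe_x` (cell centre used), `probe_index`,
#'   and `sample_dt`.
#' @export
extract_probe_series <- function(traj, x_probe = 0.5, window = NULL) {
  stopifnot(inherits(traj, "taxis_trajectory"))
  x <- traj$grid$x
  dist <- abs(x - x_probe)
  idx <- which(dist == min(dist))[1]   # tie -> lower index
  if (is.null(window)) window <- range(traj$times)
  keep <- traj$times >= window[1] - 1e-12 & traj$times <= window[2] + 1e-12
  if (!any(keep)) stop("empty probe window [", window[1], ", ", window[2], "]")
  vals <- t(vapply(traj$states[keep], function(u) u[idx, ],
                   numeric(ncol(traj$states[[1]]))))
  out <- data.frame(t = traj$times[keep], vals)
  names(out) <- c("t", paste0("u", seq_len(ncol(vals))))
  tt <- out$t
  attr(out, "probe_x") <- x[idx]
  attr(out, "probe_index") <- idx
  attr(out, "sample_dt") <- if (length(tt) > 1L) median(diff(tt)) else NA_real_
  out
}

# Local maxima of a series with quadratic (three-point) refinement of peak
# time and height; interior points only.
find_peaks <- function(s, tt) {
  n <- length(s)
  if (n < 3L) return(data.frame(t = numeric(0), height = numeric(0)))
  i <- which(s[2:(n - 1)] >= s[1:(n - 2)] & s[2:(n - 1)] > s[3:n]) + 1L
  if (!length(i)) return(data.frame(t = numeric(0), height = numeric(0)))
  a <- s[i - 1L]
  b <- s[i]
  cc <- s[i + 1L]
  den <- a - 2 * b + cc
  off <- ifelse(abs(den) > 0, 0.5 * (a - cc) / den, 0)
  off[!is.finite(off) | abs(off) > 1] <- 0
  dt <- tt[i + 1L] - tt[i]
  data.frame(t = tt[i] + off * dt,
             height = b - 0.25 * (a - cc) * off)
}

#' Classify a probe-point orbit by peak-height matching
#'
#' A series with variance below `tol_amp` is a fixed point.  Otherwise the
#' local maxima are extracted (with quadratic refinement); if all peak
#' heights agree to within `tol_match` of the series amplitude the orbit is
#' period-1; if the heights fall into 2 (or 4) repeating values it is
#' period-2 (period-4); anything else is irregular.  Fewer than
#' `min_cycles` peaks yields `"inconclusive"` rather than a guess.
#'
#' @param series numeric vector (the probe series of one population, by
#'   convention `u1`), or a data frame from [extract_probe_series()] whose
#'   `u1` column is used.
#' @param sample_dt sampling interval (taken from the series attributes
#'   when available).
#' @param tol_amp variance below which the orbit is a fixed point.
#' @param tol_match relative peak-matching tolerance, as a fraction of the
#'   series amplitude (max - min).
#' @param min_cycles minimum number of peaks required for a non-fixed-point
#'   classification.
#' @return List with `period_class` (one of `"fixed_point"`, `"period_1"`,
#'   `"period_2"`, `"period_4"`, `"irregular"`, `"inconclusive"`),
#'   `base_period` (full orbit period estimate: median inter-peak gap times
#'   the period multiplicity; NA when undefined), `peak_times`,
#'   `peak_heights`.
#' @export
classify_orbit <- function(series, sample_dt = NULL, tol_amp = 1e-6,
                           tol_match = 0.01, min_cycles = 8L) {
  if (is.data.frame(series)) {
    tt <- series$t
    s <- series$u1
  } else {
    s <- as.numeric(series)
    if (is.null(sample_dt)) stop("sample_dt required for a bare series")
    tt <- seq_along(s) * sample_dt
  }
  out <- function(class, mult, peaks) {
    base <- if (is.na(mult) || nrow(peaks) < 2L) NA_real_
            else mult * median(diff(peaks$t))
    list(period_class = class, base_period = base,
         peak_times = peaks$t, peak_heights = peaks$height)
  }
  none <- data.frame(t = numeric(0), height = numeric(0))
  if (var(s) < tol_amp) return(out("fixed_point", NA, none))
  peaks <- find_peaks(s, tt)
  K <- nrow(peaks)
  if (K < min_cycles) return(out("inconclusive", NA, peaks))
  scale <- max(s) - min(s)
  p <- peaks$height
  spread <- function(v) max(v) - min(v)
  group_spread <- function(m)
    max(vapply(seq_len(m), function(r) spread(p[seq(r, K, by = m)]),
               numeric(1)))
  if (spread(p) <= tol_match * scale) return(out("period_1", 1, peaks))
  if (K >= 2L * min_cycles && group_spread(2L) <= tol_match * scale)
    return(out("period_2", 2, peaks))
  if (K >= 4L * min_cycles && group_spread(4L) <= tol_match * scale)
    return(out("period_4", 4, peaks))
  out("irregular", NA, peaks)
}

#' Quasi-continuation sweep of a taxis coefficient
#'
#' Sweeps one entry of the taxis matrix from `from` to `to` in increments
#' of `step`.  The first stage starts from a seeded random perturbation of
#' the homogeneous state (or from `init_state`); every later stage
#' warm-starts from the final state of the previous one, approximating a
#' continuous bifurcation analysis.  Each stage integrates for
#' `t_per_stage` time units, discards the transient, samples the densities
#' at the probe point over the final `sample_window` time units, and
#' classifies the orbit with [classify_orbit()].
#'
#' @param model a [taxis_model()] template; the swept entry is overwritten
#'   per stage.
#' @param control gamma entry to sweep: index pair `c(i, j)` or string
#'   `"gamma[i][j]"`.
#' @param from,to,step sweep range and increment (`step > 0`; sweeps may
#'   run downward with `from > to`).
#' @param t_per_stage integration time per stage.
#' @param sample_window length of the sampling window at the end of each
#'   stage.
#' @param sample_dt probe sampling interval (rounded to a whole number of
#'   steps).
#' @param tau,n,scheme integration settings; the semi-implicit scheme is
#'   the default so that long sweeps run at a practical time step.
#' @param amplitude,seed initial perturbation parameters (first stage only).
#' @param probe probe location.
#' @param init_state optional [population_state()] to warm-start the first
#'   stage (e.g. the `final_state` of a previous sweep).
#' @param tol_amp,tol_match,min_cycles classification settings, see
#'   [classify_orbit()].
#' @param verbose print one line per stage.
#' @return An object of class `sweep_result`: list with `records` (one
#'   orbit record per stage: `control_value`, `probe_series`,
#'   `period_class`, `base_period`, `peak_heights`, `window_drift`),
#'   `summary` (data frame), `doubling_12`, `doubling_24` (from
#'   [locate_doubling()]), `final_state`, `control`, and `failure` (NULL,
#'   or a message when the sweep ended early on a solver failure, in which
#'   case the completed stages are still returned).
#' @export
continuation_sweep <- function(model, control = c(1, 2), from, to,
                               step = 0.05, t_per_stage = 10,
                               sample_window = 4, sample_dt = 0.002,
                               tau = 1e-4, n = 100,
                               scheme = c("semi_implicit", "explicit"),
                               amplitude = 1e-3, seed = NULL, probe = 0.5,
                               init_state = NULL, tol_amp = 1e-6,
                               tol_match = 0.01, min_cycles = 8L,
                               verbose = FALSE) {
  stopifnot(inherits(model, "taxis_model"), step > 0,
            t_per_stage > sample_window, sample_window > 0)
  scheme <- match.arg(scheme)
  ctrl <- parse_gamma_param(control, model$N)
  values <- seq(from, to, by = if (to >= from) step else -step)
  grid <- spatial_grid(n)
  state <- if (is.null(init_state)) {
    random_perturbation_ic(grid, model$N, amplitude = amplitude, seed = seed)
  } else {
    stopifnot(inherits(init_state, "population_state"))
    grid <- init_state$grid
    init_state
  }
  check_scheme(model, grid, tau, scheme)
  scheme_code <- if (scheme == "explicit") 0L else 1L
  probe_idx <- which.min(abs(grid$x - probe))[1]

  steps_per_sample <- max(1L, as.integer(round(sample_dt / tau)))
  dt_s <- steps_per_sample * tau
  n_samp <- ceiling(sample_window / dt_s)
  n_trans <- max(0L, as.integer(round((t_per_stage - sample_window) / tau)))

  records <- vector("list", length(values))
  failure <- NULL
  for (v in seq_along(values)) {
    m <- model
    m$gamma[ctrl[1], ctrl[2]] <- values[v]
    rec <- tryCatch({
      u <- state$u
      if (n_trans > 0L)
        u <- integrate_chunk(u, m, grid, tau, n_trans, scheme_code)$u
      probes <- matrix(NA_real_, n_samp + 1L, m$N)
      probes[1L, ] <- u[probe_idx, ]
      for (s in seq_len(n_samp)) {
        u <- integrate_chunk(u, m, grid, tau, steps_per_sample,
                             scheme_code)$u
        probes[s + 1L, ] <- u[probe_idx, ]
      }
      state <- as_population_state(u, grid)
      ps <- data.frame(t = (0:n_samp) * dt_s, probes)
      names(ps) <- c("t", paste0("u", seq_len(m$N)))
      cls <- classify_orbit(ps, tol_amp = tol_amp, tol_match = tol_match,
                            min_cycles = min_cycles)
      half <- ps$u1[seq_len(n_samp %/% 2)]
      half2 <- ps$u1[(n_samp %/% 2 + 1L):nrow(ps)]
      drift <- abs(mean(half2) - mean(half)) +
        abs((max(half2) - min(half2)) - (max(half) - min(half)))
      list(control_value = values[v], probe_series = ps,
           period_class = cls$period_class, base_period = cls$base_period,
           peak_heights = cls$peak_heights, peak_times = cls$peak_times,
           window_drift = drift)
    }, error = function(e) {
      failure <<- paste0("stage at control = ", values[v], ": ",
                         conditionMessage(e))
      NULL
    })
    if (is.null(rec)) break
    records[[v]] <- rec
    if (verbose)
      message(sprintf("control = %.4g: %s (base period %.4g)",
                      values[v], rec$period_class, rec$base_period))
  }
  records <- Filter(Negate(is.null), records)
  summary <- data.frame(
    control_value = vapply(records, `[[`, numeric(1), "control_value"),
    period_class = vapply(records, `[[`, character(1), "period_class"),
    base_period = vapply(records, `[[`, numeric(1), "base_period"),
    n_peaks = vapply(records, function(r) length(r$peak_heights),
                     integer(1)),
    window_drift = vapply(records, `[[`, numeric(1), "window_drift"))
  res <- structure(list(records = records, summary = summary,
                        control = ctrl, step = step,
                        final_state = state, failure = failure),
                   class = "sweep_result")
  res$doubling_12 <- locate_doubling(res, "1->2")
  res$doubling_24 <- locate_doubling(res, "2->4")
  res
}

#' @export
print.sweep_result <- function(x, ...) {
  cat("Quasi-continuation sweep of gamma[", x$control[1], "][",
      x$control[2], "]: ", nrow(x$summary), " stages\n", sep = "")
  print(x$summary[, c("control_value", "period_class", "base_period")],
        row.names = FALSE)
  if (!is.null(x$failure)) cat("  FAILURE:", x$failure, "\n")
  invisible(x)
}

#' Locate a period-doubling transition in a sweep
#'
#' Finds the bracketing interval where the orbit class first changes from
#' the lower to the higher period: the upper end is the first control value
#' classified with the higher period, the lower end the last preceding
#' value with the lower period.  The point estimate is the midpoint; the
#' bracket width equals the sweep step by construction when the transition
#' is clean.
#'
#' @param sweep a `sweep_result` (or anything with a `summary` data frame
#'   holding `control_value` and `period_class`).
#' @param transition `"1->2"` or `"2->4"`.
#' @return List with `found` (logical), `lower`, `upper`, `estimate`
#'   (midpoint) and `width`; the numeric fields are NA when the transition
#'   is absent.
#' @export
locate_doubling <- function(sweep, transition = c("1->2", "2->4")) {
  transition <- match.arg(transition)
  lower_class <- if (transition == "1->2") "period_1" else "period_2"
  higher_class <- if (transition == "1->2") "period_2" else "period_4"
  s <- sweep$summary
  not_found <- list(found = FALSE, lower = NA_real_, upper = NA_real_,
                    estimate = NA_real_, width = NA_real_,
                    transition = transition)
  j <- which(s$period_class == higher_class)
  if (!length(j)) return(not_found)
  j <- j[1]
  i <- which(s$period_class == lower_class & seq_len(nrow(s)) < j)
  if (!length(i)) return(not_found)
  i <- i[length(i)]
  list(found = TRUE, lower = s$control_value[i],
       upper = s$control_value[j],
       estimate = (s$control_value[i] + s$control_value[j]) / 2,
       width = s$control_value[j] - s$control_value[i],
       transition = transition)
}

period_rank <- function(class) {
  unname(c(fixed_point = 0, period_1 = 1, period_2 = 2, period_4 = 3,
           irregular = 4, inconclusive = NA_real_)[class])
}

#' Locate the period-doubling cascade of the three-population template
#'
#' Runs the full quasi-continuation protocol used to localise the two
#' period-doubling transitions of the oscillatory three-population system.
#' Because several attractor branches coexist (standing-wave-like and
#' travelling-wave-like oscillations, which lose stability at different
#' control values), the first doubling is estimated over an ensemble of
#' `n_subseeds` sweeps from independent random initial conditions: each
#' sweep climbs from `from` in steps of `step` until its orbit first leaves
#' the period-1 class (or `cap` is reached), and the smallest transition
#' point across the ensemble -- the first control value at which a
#' period-doubled orbit is observed on any sampled branch -- is reported as
#' the first doubling.  The branch achieving it is then continued upward to
#' `t2_to`; the second doubling is the period-2 to period-4 bracket on that
#' path when the period-4 class is observed, and otherwise the first
#' departure from period-2 (near the accumulation of the cascade the
#' successor attractor may already classify as irregular at this sweep
#' resolution).
#'
#' @param model template [taxis_model()] (the three-population setting of
#'   the regime map, with the swept entry overwritten).
#' @param seed integer seed; sub-seeds for the ensemble are drawn from it
#'   reproducibly.
#' @param control swept gamma entry.
#' @param from,cap first-doubling sweep range.
#' @param t2_to upper end of the second-doubling continuation.
#' @param step,t_per_stage,sample_window,sample_dt,tau,n,scheme,amplitude
#'   sweep settings, see [continuation_sweep()].
#' @param n_subseeds ensemble size.
#' @param verbose print per-stage progress.
#' @return List with `t1` (first-doubling midpoint), `t1_bracket`,
#'   `t1_per_seed` (data frame of per-sub-seed estimates), `t2`,
#'   `t2_bracket`, `t2_transition` (`"period_2 -> period_4"` or the
#'   observed class change), and `path2` (summary data frame of the
#'   second-doubling continuation).
#' @export
cascade_analysis <- function(model, seed, control = c(1, 2), from = 3.8,
                             cap = 5.3, t2_to = 6.1, step = 0.05,
                             t_per_stage = 10, sample_window = 4,
                             sample_dt = 0.002, tau = 5e-5, n = 100,
                             scheme = "semi_implicit", amplitude = 1e-3,
                             n_subseeds = 3, verbose = FALSE) {
  sub_seeds <- with_seed(seed, sample.int(1e6, n_subseeds))
  seg <- 4L * step                      # sweep segment length (4 stages)
  run_until_departure <- function(sub_seed) {
    st <- NULL
    tab <- NULL
    for (seg_start in seq(from, cap, by = seg)) {
      sw <- continuation_sweep(model, control = control, from = seg_start,
                               to = min(seg_start + seg - step, cap),
                               step = step, t_per_stage = t_per_stage,
                               sample_window = sample_window,
                               sample_dt = sample_dt, tau = tau, n = n,
                               scheme = scheme, amplitude = amplitude,
                               seed = sub_seed, init_state = st,
                               verbose = verbose)
      st <- sw$final_state
      tab <- rbind(tab, sw$summary)
      rk <- period_rank(tab$period_class)
      dep <- which(rk > 1)
      if (length(dep) && any(rk[seq_len(dep[1] - 1L)] == 1)) {
        i <- dep[1]
        return(list(found = TRUE,
                    lower = tab$control_value[i - 1L],
                    upper = tab$control_value[i],
                    estimate = (tab$control_value[i - 1L] +
                                  tab$control_value[i]) / 2,
                    state = st, control_at = tab$control_value[i],
                    summary = tab))
      }
    }
    list(found = FALSE, lower = NA_real_, upper = NA_real_,
         estimate = NA_real_, state = st,
         control_at = tab$control_value[nrow(tab)], summary = tab)
  }

  runs <- lapply(sub_seeds, run_until_departure)
  per_seed <- data.frame(sub_seed = sub_seeds,
                         found = vapply(runs, `[[`, logical(1), "found"),
                         estimate = vapply(runs, `[[`, numeric(1),
                                           "estimate"))
  if (any(per_seed$found)) {
    best <- which.min(ifelse(per_seed$found, per_seed$estimate, Inf))
  } else {
    best <- 1L                          # no branch doubled below the cap
  }
  b <- runs[[best]]

  # continue the doubling branch upward for the second transition
  sw2 <- continuation_sweep(model, control = control,
                            from = b$control_at + step, to = t2_to,
                            step = step, t_per_stage = t_per_stage,
                            sample_window = sample_window,
                            sample_dt = sample_dt, tau = tau, n = n,
                            scheme = scheme, init_state = b$state,
                            verbose = verbose)
  path2 <- rbind(b$summary, sw2$summary)
  strict <- locate_doubling(list(summary = path2), "2->4")
  if (strict$found) {
    t2 <- strict$estimate
    t2_bracket <- c(strict$lower, strict$upper)
    t2_transition <- "period_2 -> period_4"
  } else {
    rk <- period_rank(path2$period_class)
    dep <- which(rk > 2 & seq_along(rk) > which(rk == 2)[1])
    if (length(which(rk == 2)) && length(dep)) {
      i <- dep[1]
      t2 <- (path2$control_value[i - 1L] + path2$control_value[i]) / 2
      t2_bracket <- path2$control_value[c(i - 1L, i)]
      t2_transition <- paste(path2$period_class[i - 1L], "->",
                             path2$period_class[i])
    } else {
      t2 <- NA_real_
      t2_bracket <- c(NA_real_, NA_real_)
      t2_transition <- "not found"
    }
  }
  list(t1 = if (b$found) b$estimate else NA_real_,
       t1_bracket = c(b$lower, b$upper), t1_per_seed = per_seed,
       t2 = t2, t2_bracket = t2_bracket, t2_transition = t2_transition,
       path2 = path2)
}
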