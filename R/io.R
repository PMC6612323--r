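# Configuration parsing and CSV interchange.  A single JSON config file is
# the source of truth for all command-line entry points: a `model` block
# (or a dimensional `scenario` block), a `numerics` block and an optional
# `analysis` block.  All results travel as long-format CSV with a comment
# header recording the config hash and seed, written at full float
# precision so round-trips are lossless.

reject_unknown <- function(block, allowed, where) {
  extra <- setdiff(names(block), allowed)
  if (length(extra))
    stop("config: unknown key(s) ", paste0(where, ".", extra,
                                           collapse = ", "))
  invisible(block)
}

get_num <- function(block, key, where, default = NULL, min = -Inf,
                    max = Inf) {
  v <- block[[key]]
  if (is.null(v)) {
    if (is.null(default))
      stop("config: missing required key ", where, ".", key)
    return(default)
  }
  if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v < min ||
      v > max)
    stop("config: ", where, ".", key, " must be a number in [",
         min, ", ", max, "]")
  v
}

#' Load and validate a run configuration
#'
#' Reads a JSON configuration with blocks `model` (keys `d`, `gamma` as a
#' list of rows, `delta`, optional `kernel`) or `scenario` (dimensional
#' parameters passed through [nondimensionalize()]: `scenario`, `L`, `D`,
#' `c`, `A`, optional `mu`/`nu`/`zeta`, plus `delta`), `numerics`
#' (defaults: `n = 100`, `dt = 1e-5`, `t_end = 10`, `sample_every = 0.01`,
#' `scheme = "explicit"`, `seed = 1`, `amplitude = 1e-3`) and an optional
#' free-form `analysis` block (`kappa_max`, `kappa_n`, `probe`, `scan`,
#' `sweep`).  Unknown keys anywhere are rejected with their key path.
#'
#' @param path path to the JSON file.
#' @return An object of class `run_config`: list with `model` (a
#'   [taxis_model()]), `numerics`, `analysis`.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  cfg <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  reject_unknown(cfg, c("model", "scenario", "numerics", "analysis"),
                 "config")
  if (is.null(cfg$model) && is.null(cfg$scenario))
    stop("config: needs a 'model' or 'scenario' block")

  if (!is.null(cfg$model)) {
    mb <- reject_unknown(cfg$model, c("N", "d", "gamma", "delta", "kernel"),
                         "model")
    if (is.null(mb$d) || is.null(mb$gamma) || is.null(mb$delta))
      stop("config: model block needs keys d, gamma, delta")
    gamma <- mb$gamma
    if (is.list(gamma)) gamma <- do.call(rbind, gamma)
    model <- taxis_model(d = mb$d, gamma = gamma, delta = mb$delta,
                         kernel = if (is.null(mb$kernel)) "top_hat"
                                  else mb$kernel)
    if (!is.null(mb$N) && mb$N != model$N)
      stop("config: model.N = ", mb$N, " does not match length(d) = ",
           model$N)
  } else {
    sb <- reject_unknown(cfg$scenario,
                         c("scenario", "L", "D", "c", "A", "mu", "nu",
                           "zeta", "delta"), "scenario")
    A <- sb$A
    if (is.list(A)) A <- do.call(rbind, A)
    params <- scenario_params(scenario = sb$scenario, L = sb$L, D = sb$D,
                              c = sb$c, A = A, mu = sb$mu, nu = sb$nu,
                              zeta = if (is.null(sb$zeta)) 0 else sb$zeta)
    model <- nondimensionalize(params,
                               delta = get_num(sb, "delta", "scenario",
                                               min = 0, max = 0.5))
  }

  nb <- if (is.null(cfg$numerics)) list() else cfg$numerics
  reject_unknown(nb, c("n", "dt", "t_end", "sample_every", "scheme",
                       "seed", "amplitude"), "numerics")
  numerics <- list(
    n = as.integer(get_num(nb, "n", "numerics", default = 100, min = 16)),
    dt = get_num(nb, "dt", "numerics", default = 1e-5, min = 1e-12),
    t_end = get_num(nb, "t_end", "numerics", default = 10, min = 1e-12),
    sample_every = get_num(nb, "sample_every", "numerics", default = 0.01,
                           min = 1e-12),
    scheme = if (is.null(nb$scheme)) "explicit"
             else match.arg(nb$scheme, c("explicit", "semi_implicit")),
    seed = as.integer(get_num(nb, "seed", "numerics", default = 1)),
    amplitude = get_num(nb, "amplitude", "numerics", default = 1e-3,
                        min = 0, max = 1))

  ab <- if (is.null(cfg$analysis)) list() else cfg$analysis
  reject_unknown(ab, c("kappa_max", "kappa_n", "probe", "scan", "sweep"),
                 "analysis")
  analysis <- list(
    kappa_max = get_num(ab, "kappa_max", "analysis", default = 100,
                        min = 0),
    kappa_n = as.integer(get_num(ab, "kappa_n", "analysis", default = 400,
                                 min = 2)),
    probe = get_num(ab, "probe", "analysis", default = 0.5, min = 0,
                    max = 1),
    scan = ab$scan, sweep = ab$sweep)

  structure(list(model = model, numerics = numerics, analysis = analysis),
            class = "run_config")
}

# Tiny FNV-1a hash over a character representation, for provenance comment
# lines (no cryptographic intent).
fnv1a_hash <- function(x) {
  bytes <- utf8ToInt(paste(deparse(x), collapse = ""))
  h <- 2166136261
  for (b in bytes) {
    h <- bitwXor(as.integer(h %% 2^31), b)
    h <- (h * 16777619) %% 2^31
  }
  sprintf("%08x", as.integer(h))
}

fmt17 <- function(x) {
  if (is.numeric(x) && !is.integer(x)) sprintf("%.17g", x) else as.character(x)
}

write_csv_precise <- function(df, path, meta = character()) {
  con <- file(path, "w")
  on.exit(close(con))
  for (nm in names(meta))
    writeLines(paste0("# ", nm, "=", meta[[nm]]), con)
  writeLines(paste(names(df), collapse = ","), con)
  cols <- lapply(df, fmt17)
  if (nrow(df))
    writeLines(do.call(paste, c(cols, sep = ",")), con)
  invisible(path)
}

read_csv_meta <- function(path) {
  if (!file.exists(path)) stop("result file not found: ", path)
  lines <- readLines(path)
  meta_lines <- grep("^# ", lines, value = TRUE)
  meta <- list()
  for (ln in meta_lines) {
    kv <- sub("^# ", "", ln)
    eq <- regexpr("=", kv, fixed = TRUE)
    meta[[substr(kv, 1, eq - 1)]] <- substr(kv, eq + 1, nchar(kv))
  }
  df <- read.csv(text = lines[!startsWith(lines, "# ")],
                 stringsAsFactors = FALSE)
  list(df = df, meta = meta)
}

#' Write / read a trajectory as long-format CSV
#'
#' Columns `t`, `population`, `cell_index`, `x`, `u`, at full float
#' precision (lossless round-trip).  Comment lines record the seed (when
#' given), grid size, time step, scheme and a config hash.
#'
#' @param traj a `taxis_trajectory`.
#' @param path output file.
#' @param seed optional seed recorded in the header.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(traj, path, seed = NULL) {
  stopifnot(inherits(traj, "taxis_trajectory"))
  n <- traj$grid$n
  N <- ncol(traj$states[[1]])
  rows <- lapply(seq_along(traj$times), function(s) {
    data.frame(t = traj$times[s],
               population = rep(seq_len(N), each = n),
               cell_index = rep(seq_len(n), N),
               x = rep(traj$grid$x, N),
               u = as.vector(traj$states[[s]]))
  })
  meta <- c(config_hash = fnv1a_hash(traj$model),
            n = n, tau = fmt17(traj$tau), scheme = traj$scheme,
            status = traj$status)
  if (!is.null(seed)) meta["seed"] <- seed
  write_csv_precise(do.call(rbind, rows), path, meta)
}

#' @rdname write_trajectory
#' @param model optional [taxis_model()] attached to the reconstructed
#'   trajectory (the config file, not the CSV, is the model's source of
#'   truth).
#' @export
read_trajectory <- function(path, model = NULL) {
  r <- read_csv_meta(path)
  df <- r$df
  n <- as.integer(r$meta$n)
  grid <- spatial_grid(n)
  times <- as.numeric(unique(df$t))
  N <- max(df$population)
  states <- lapply(unique(df$t), function(tv) {
    matrix(as.numeric(df$u[df$t == tv]), nrow = n, ncol = N)
  })
  structure(list(times = times, states = states,
                 diagnostics = NULL, model = model, grid = grid,
                 tau = as.numeric(r$meta$tau), scheme = r$meta$scheme,
                 sample_every = if (length(times) > 1)
                   median(diff(times)) else NA_real_,
                 status = r$meta$status),
            class = "taxis_trajectory")
}

#' Write / read a dispersion relation as CSV
#'
#' Columns `kappa`, `re_sigma`, `im_sigma`; the regime and most unstable
#' wavenumber travel as comment lines.
#'
#' @param disp a `dispersion_result`.
#' @param path file path.
#' @return `path` invisibly (write); a `dispersion_result` without the
#'   model attached (read).
#' @export
write_dispersion <- function(disp, path) {
  stopifnot(inherits(disp, "dispersion_result"))
  write_csv_precise(as.data.frame(disp), path,
                    meta = c(config_hash = fnv1a_hash(disp$model),
                             regime = disp$regime,
                             kappa_star = fmt17(disp$kappa_star)))
}

#' @rdname write_dispersion
#' @export
read_dispersion <- function(path) {
  r <- read_csv_meta(path)
  structure(list(kappa = as.numeric(r$df$kappa),
                 re_sigma = as.numeric(r$df$re_sigma),
                 im_sigma = as.numeric(r$df$im_sigma),
                 kappa_star = as.numeric(r$meta$kappa_star),
                 regime = r$meta$regime, model = NULL),
            class = "dispersion_result")
}

#' Write / read a regime map as long-format CSV
#'
#' Columns `p1`, `p2`, `regime`.
#'
#' @param map a `regime_map`.
#' @param path file path.
#' @return `path` invisibly (write); a `regime_map` (read).
#' @export
write_regime_map <- function(map, path) {
  stopifnot(inherits(map, "regime_map"))
  df <- data.frame(p1 = rep(map$grid1, times = length(map$grid2)),
                   p2 = rep(map$grid2, each = length(map$grid1)),
                   regime = as.vector(map$regimes))
  write_csv_precise(df, path, meta = c(
    param1 = paste0("gamma[", map$param1[1], "][", map$param1[2], "]"),
    param2 = paste0("gamma[", map$param2[1], "][", map$param2[2], "]"),
    delta_mode = map$delta_mode))
}

#' @rdname write_regime_map
#' @export
read_regime_map <- function(path) {
  r <- read_csv_meta(path)
  grid1 <- as.numeric(unique(r$df$p1))
  grid2 <- as.numeric(unique(r$df$p2))
  structure(list(param1 = parse_gamma_param(r$meta$param1, Inf),
                 param2 = parse_gamma_param(r$meta$param2, Inf),
                 grid1 = grid1, grid2 = grid2,
                 regimes = matrix(r$df$regime, nrow = length(grid1),
                                  ncol = length(grid2)),
                 delta_mode = r$meta$delta_mode),
            class = "regime_map")
}

#' Write / read a continuation-sweep summary as CSV
#'
#' Columns `control_value`, `period_class`, `base_period`, `n_peaks`,
#' `window_drift`, `peak_heights` (semicolon-joined, full precision).  With
#' `orbit_dir` set, each stage's probe series is additionally written to
#' `orbit_dir/orbit_<control>.csv`.
#'
#' @param sweep a `sweep_result`.
#' @param path summary file path.
#' @param orbit_dir optional directory for per-stage probe series.
#' @return `path` invisibly (write); for the reader, a list with `summary`
#'   (data frame including parsed `peak_heights`).
#' @export
write_sweep <- function(sweep, path, orbit_dir = NULL) {
  stopifnot(inherits(sweep, "sweep_result"))
  df <- sweep$summary
  df$peak_heights <- vapply(sweep$records, function(r)
    paste(fmt17(r$peak_heights), collapse = ";"), character(1))
  meta <- c(control = paste0("gamma[", sweep$control[1], "][",
                             sweep$control[2], "]"),
            step = fmt17(sweep$step))
  if (!is.null(sweep$failure)) meta["failure"] <- sweep$failure
  if (!is.null(orbit_dir)) {
    dir.create(orbit_dir, showWarnings = FALSE, recursive = TRUE)
    for (r in sweep$records)
      write_csv_precise(r$probe_series,
                        file.path(orbit_dir,
                                  sprintf("orbit_%s.csv",
                                          format(r$control_value))))
  }
  write_csv_precise(df, path, meta)
}

#' @rdname write_sweep
#' @export
read_sweep <- function(path) {
  r <- read_csv_meta(path)
  df <- r$df
  ph <- as.character(df$peak_heights)
  ph[is.na(ph)] <- ""
  peaks <- lapply(strsplit(ph, ";", fixed = TRUE), as.numeric)
  df$control_value <- as.numeric(df$control_value)
  df$base_period <- as.numeric(df$base_period)
  df$peak_heights <- NULL
  list(summary = df, peak_heights = peaks, control = r$meta$control,
       step = as.numeric(r$meta$step), failure = r$meta$failure)
}
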