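# Run configuration (YAML/JSON), deterministic fixture generation and
# figure-table export.

config_schema <- function() {
  list(
    geometry = list(shape = "integer vector (1-3 axes)",
                    dx = "numeric (cm)"),
    model = list(variant = "healthy|cAF", ik1_remodeling = "scale|add",
                 fca_scaled = "logical"),
    thermal = list(rho = "numeric", C = "numeric", kt = "numeric",
                   spots = "list of {center, radius, T_spot, t_on, t_off}",
                   mode_2d = "step|diffusive"),
    stimulus = list(s1 = "list", s2 = "list", amp = "numeric|NULL"),
    drag = list(radius = "numeric", T_spot = "numeric",
                move_step = "numeric", dwell_rotations = "numeric",
                transmural_dwell = "logical", max_moves = "integer"),
    numerics = list(dt_ep = "numeric (ms)", dt_heat = "numeric (s)|NULL",
                    dx = "numeric (cm)", D = "numeric (cm^2/ms)",
                    nernst_every = "integer"),
    outputs = list(snap_every = "numeric (ms)", dir = "character"),
    seed = "integer"
  )
}

config_defaults <- function() {
  list(
    geometry = list(shape = c(251L, 251L), dx = 0.03),
    model = list(variant = "healthy", ik1_remodeling = "scale",
                 fca_scaled = FALSE),
    thermal = list(rho = 1050, C = 4219, kt = 0.7, spots = list(),
                   mode_2d = "step"),
    stimulus = list(s1 = NULL, s2 = NULL, amp = NULL),
    drag = list(radius = 0.9, T_spot = 5, move_step = 1,
                dwell_rotations = 2, transmural_dwell = TRUE,
                max_moves = 12L),
    numerics = list(dt_ep = 0.02, dt_heat = NA_real_, dx = 0.03, D = 0.0025,
                    nernst_every = 1L),
    outputs = list(snap_every = 10, dir = "."),
    seed = 1L
  )
}

#' Validate and resolve a run configuration
#'
#' Reads a YAML or JSON run configuration (or an already-parsed list),
#' rejects unknown keys, fills every missing value with the package defaults
#' (the published model constants: dt = 0.02 ms, dx = 0.03 cm,
#' D = 0.0025 cm^2/ms, the thermal constants, the 9-mm 5-degC spot), and
#' pre-checks the explicit stability bounds.
#'
#' @param x path to a YAML/JSON file, a YAML string, or a named list.
#' @return the fully resolved configuration (class `run_config`).  Schema
#'   violations raise errors naming the offending key and constraint.
#' @export
validate_config <- function(x = list()) {
  if (is.character(x)) {
    x <- if (file.exists(x)) {
      if (grepl("\\.json$", x)) jsonlite::fromJSON(x, simplifyVector = TRUE)
      else yaml::read_yaml(x)
    } else yaml::yaml.load(x)
    if (is.null(x)) x <- list()
  }
  stopifnot(is.list(x))
  def <- config_defaults()
  unknown <- setdiff(names(x), names(def))
  if (length(unknown))
    stop("unknown configuration key: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  for (sec in names(x)) {
    if (is.list(def[[sec]]) && !is.null(x[[sec]])) {
      bad <- setdiff(names(x[[sec]]), names(def[[sec]]))
      if (length(bad))
        stop("unknown configuration key: ", sec, "$",
             paste(bad, collapse = ", "), call. = FALSE)
    }
  }
  cfg <- utils::modifyList(def, x)
  # constraint checks
  if (cfg$numerics$dt_ep > 0.02)
    stop("numerics$dt_ep = ", cfg$numerics$dt_ep,
         " ms exceeds the explicit limit 0.02 ms", call. = FALSE)
  nd <- length(cfg$geometry$shape)
  cfl <- cfg$numerics$D * cfg$numerics$dt_ep / cfg$numerics$dx^2
  if (cfl > 1 / (2 * nd))
    stop(sprintf("numerics: D dt/dx^2 = %.3f violates the bound %.3f",
                 cfl, 1 / (2 * nd)), call. = FALSE)
  if (!cfg$model$variant %in% c("healthy", "cAF"))
    stop("model$variant must be healthy or cAF", call. = FALSE)
  if (!is.null(cfg$numerics$dt_heat) && !is.na(cfg$numerics$dt_heat)) {
    props <- thermal_properties(cfg$thermal$rho, cfg$thermal$C,
                                cfg$thermal$kt)
    h <- cfg$numerics$dx / 100
    dmax <- 1 / (2 * props$kappa * nd / h^2)
    if (cfg$numerics$dt_heat > dmax)
      stop(sprintf("numerics$dt_heat = %g s exceeds the stability bound %g s",
                   cfg$numerics$dt_heat, dmax), call. = FALSE)
  }
  cfg$seed <- as.integer(cfg$seed)
  structure(cfg, class = "run_config")
}

#' Write a resolved configuration beside run outputs
#'
#' @param cfg a `run_config`.
#' @param path output file (YAML).
#' @return the path, invisibly.
#' @export
write_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' Deterministic test fixtures with known ground truth
#'
#' Generates the small synthetic inputs used by the test-suite and examples:
#' \describe{
#'   \item{`synthetic-ap-trace`}{a ramp action potential (instant rise
#'     -80 to +20 mV, linear fall back over 100 ms) whose APD_X are known in
#'     closed form (APD90 = 90 ms).}
#'   \item{`rotating-phase-field`}{two snapshots of
#'     `V = V0 + A cos(atan2(y-y0, x-x0) - w t)` with a known phase
#'     singularity of charge +1 at the center.}
#'   \item{`extruded-spiral-volume`}{a 3D volume whose layers all replicate
#'     the rotating field: a straight transmural filament.}
#'   \item{`small-heat-slab`}{a 1D slab with ends at 5 and 37 degC whose
#'     steady state is the linear profile.}
#' }
#'
#' @param kind fixture kind (see above).
#' @param seed integer seed stamped into the fixture (noise, if any).
#' @param n grid size/samples.
#' @param noise optional Gaussian noise SD added to field fixtures.
#' @return list with the fixture data and its `truth` (closed-form ground
#'   truth); deterministic for a given seed.
#' @export
generate_fixtures <- function(kind = c("synthetic-ap-trace",
                                       "rotating-phase-field",
                                       "extruded-spiral-volume",
                                       "small-heat-slab"),
                              seed = 1L, n = 41L, noise = 0) {
  kind <- match.arg(kind)
  set.seed(seed)
  out <- switch(kind,
    "synthetic-ap-trace" = {
      # instant rise -80 -> +20 at t = 10, linear fall to -80 over 100 ms:
      # APD_X = X ms by construction (amplitude 100 mV, 1 mV/ms fall)
      t <- seq(0, 150, by = 0.5)
      V <- rep(-80, length(t))
      up <- t >= 10 & t <= 110
      V[up] <- 20 - (t[up] - 10)
      V[t < 10] <- -80
      V <- V + if (noise > 0) stats::rnorm(length(t), 0, noise) else 0
      list(trace = data.frame(t = t, V = V),
           truth = list(APD40 = 40, APD50 = 50, APD90 = 90, RMP = -80,
                        peak = 20))
    },
    "rotating-phase-field" = {
      co <- seq_len(n) - (n + 1) / 2
      ang <- outer(co, co, function(a, b) atan2(b, a))
      mk <- function(phase) -40 + 30 * cos(ang - phase) +
        if (noise > 0) matrix(stats::rnorm(n * n, 0, noise), n, n) else 0
      list(V1 = mk(0), V2 = mk(0.4), n = n,
           truth = list(x0 = (n - 1) / 2 * 0.03, y0 = (n - 1) / 2 * 0.03,
                        charge = 1))
    },
    "extruded-spiral-volume" = {
      co <- seq_len(n) - (n + 1) / 2
      ang <- outer(co, co, function(a, b) atan2(b, a))
      nz <- 5L
      mk <- function(phase) {
        A <- array(0, c(n, n, nz))
        for (k in seq_len(nz)) A[, , k] <- -40 + 30 * cos(ang - phase)
        A
      }
      list(A1 = mk(0), A2 = mk(0.4), n = n, nz = nz,
           truth = list(transmural = TRUE, length = (nz - 1) * 0.03))
    },
    "small-heat-slab" = {
      # 2D slab whose top face is fully covered by a 5-degC spot: the steady
      # state is the 1D linear conduction profile through the thickness
      nz <- n
      wid <- (nz - 1) * 0.03125
      list(field = temperature_field(c(nz, nz), spacing = 0.03125, T = 37),
           spot = cold_spot(center = wid / 2, radius = wid, T_spot = 5),
           center_index = (nz + 1) %/% 2,
           truth = list(steady = seq(5, 37, length.out = nz)))
    })
  out$seed <- seed
  out$kind <- kind
  out
}

#' Single-cell temperature sweep
#'
#' Equilibrates and stimulates the cell across a set of temperatures and
#' collects the full metric table: RMP and its shift, APD40/50/90 and their
#' ratios to 37 degC, the Ca-transient peak, and the peak value of each of
#' the 12 membrane currents with its relative change I_ratio.
#'
#' @param params a `crn_params`.
#' @param temperatures degC vector; 37 is added if absent (the baseline).
#' @param duration trace length per run (ms); long enough to cover the cold
#'   prolonged APs.
#' @param q10s a `q10_set`.
#' @return data.frame, one row per temperature (the machine-readable
#'   single-cell figure table).
#' @export
temperature_sweep <- function(params, temperatures = c(5, 10, 15, 20, 25,
                                                       30, 37),
                              duration = NULL, q10s = q10_set()) {
  temperatures <- sort(unique(c(temperatures, 37)))
  one <- function(T) {
    dur <- if (!is.null(duration)) duration
           else if (T < 10) 12000 else if (T < 20) 6000 else 1500
    r <- run_cell(params, T, duration = dur, stim_times = 10,
                  record_currents = TRUE, record_every = 5, q10s = q10s)
    m <- ap_metrics(r$trace, stim_times = 10)
    peaks <- vapply(CURRENT_NAMES, function(cn) {
      v <- r$trace[[cn]]
      v[which.max(abs(v))]
    }, numeric(1))
    c(T = T, RMP = m$RMP, peak = m$peak, m$apd,
      CaT_peak = m$cat_peak, peaks)
  }
  rows <- lapply(temperatures, one)
  df <- as.data.frame(do.call(rbind, rows))
  base <- df[df$T == 37, ]
  df$dRMP <- df$RMP - base$RMP
  for (X in c(40, 50, 90))
    df[[paste0("APD", X, "_ratio")]] <- df[[paste0("APD", X)]] /
      base[[paste0("APD", X)]]
  for (cn in CURRENT_NAMES)
    df[[paste0("Iratio_", cn)]] <- current_ratio(df[[cn]], base[[cn]])
  df
}

#' Export the single-cell figure tables
#'
#' Writes one tidy CSV per panel of the single-cell temperature study:
#' `drmp_vs_T.csv` (RMP shift), `apd_ratios_vs_T.csv`, and
#' `iratio_vs_T.csv` (per-current relative peak changes).
#'
#' @param sweep a [temperature_sweep()] result.
#' @param dir output directory.
#' @return invisibly, the written paths.  An incomplete sweep (fewer than two
#'   temperatures) still writes what it has, with a warning.
#' @export
export_figure_tables <- function(sweep, dir = ".") {
  if (nrow(sweep) < 2)
    warning("sweep has fewer than two temperatures; tables will be partial")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p1 <- file.path(dir, "drmp_vs_T.csv")
  utils::write.csv(sweep[, c("T", "RMP", "dRMP")], p1, row.names = FALSE)
  p2 <- file.path(dir, "apd_ratios_vs_T.csv")
  utils::write.csv(sweep[, c("T", "APD40", "APD50", "APD90",
                             "APD40_ratio", "APD50_ratio", "APD90_ratio")],
                   p2, row.names = FALSE)
  p3 <- file.path(dir, "iratio_vs_T.csv")
  utils::write.csv(sweep[, c("T", CURRENT_NAMES,
                             paste0("Iratio_", CURRENT_NAMES))],
                   p3, row.names = FALSE)
  invisible(c(p1, p2, p3))
}
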