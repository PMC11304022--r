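# Monodomain tissue: geometry, per-node cell states with local temperature,
# explicit reaction-diffusion stepping, conduction-velocity measurement and
# S1-S2 cross-field reentry induction.

#' Tissue geometry
#'
#' @param shape node counts per axis (1, 2 or 3 axes; >= 3 each).
#' @param dx spatial resolution (cm), default 0.03.
#' @return object of class `tissue_geometry` with `shape`, `dx`, `ndim`,
#'   `N` and the physical `size` (cm).
#' @export
tissue_geometry <- function(shape, dx = 0.03) {
  shape <- as.integer(shape)
  stopifnot(length(shape) %in% 1:3, all(shape >= 3), dx > 0)
  structure(list(shape = shape, dx = dx, ndim = length(shape),
                 N = prod(shape), size = (shape - 1L) * dx),
            class = "tissue_geometry")
}

#' Tissue state: per-node membrane states with local temperature
#'
#' Builds the full state of a monodomain simulation: one CRN state per node
#' (initialized from the equilibrated resting state at each node's
#' temperature), the temperature field and the per-node kinetics scalers
#' derived from it, and the diffusion constant.
#'
#' @param geometry a [tissue_geometry()].
#' @param params a `crn_params`.
#' @param T temperature (degC): scalar or per-node vector/array.
#' @param D diffusion constant (cm^2/ms), default 0.0025.
#' @param q10s a `q10_set`.
#' @return object of class `tissue_state`: environment-free list with the
#'   21 x N state matrix `S`, `temp` (per-node degC), `geometry`, `D`,
#'   `params`, `q10s`, simulated time `t` (ms) and bookkeeping caches.
#' @export
tissue_state <- function(geometry, params, T = 37, D = 0.0025,
                         q10s = q10_set()) {
  stopifnot(inherits(geometry, "tissue_geometry"), D >= 0)
  temp <- rep_len(as.numeric(T), geometry$N)
  st <- list(geometry = geometry, params = params, q10s = q10s, D = D,
             t = 0, temp = NULL, S = NULL, groups = NULL, scalers = NULL,
             thermo = NULL, rtf = NULL)
  # seed every node with the equilibrated state of its (quantized) temperature
  S <- matrix(0, 21, geometry$N)
  for (Tq in unique(round(temp, 1))) {
    eq <- equilibrate(params, Tq, q10s = q10s)
    S[, round(temp, 1) == Tq] <- as.numeric(eq$state)
  }
  st$S <- S
  st <- set_temperature(st, temp)
  class(st) <- "tissue_state"
  st
}

#' Impose a temperature field on a tissue state
#'
#' Updates the per-node temperature and rebuilds the per-node kinetics
#' scalers and thermodynamic lookup tables (cached per 0.1-degC-quantized
#' temperature).
#'
#' @param state a [tissue_state()].
#' @param temp per-node temperature (degC), scalar recycled.
#' @return the updated state.
#' @export
set_temperature <- function(state, temp) {
  N <- state$geometry$N
  temp <- rep_len(as.numeric(temp), N)
  tq <- round(temp, 1)
  levs <- sort(unique(tq))
  state$temp <- temp
  state$groups <- match(tq, levs) - 1L           # 0-based for C++
  luts <- lapply(levs, thermo_lut)
  state$thermo <- do.call(cbind, luts)           # nV x (3 * ngroups)
  state$rtf <- vapply(luts, function(l) attr(l, "rtf"), numeric(1))
  sc <- vapply(levs, function(Tq)
    kernel_scalers(state$params, state$q10s, Tq), numeric(7))
  if (is.null(dim(sc))) sc <- matrix(sc, 7)
  state$group_scalers <- sc                      # 7 x ngroups
  state$group_temps <- levs
  state$scalers <- sc[, state$groups + 1L, drop = FALSE]  # 7 x N
  state["explut"] <- list(NULL)                  # invalidated; dt-specific
  state
}

# per-group Rush-Larsen exponential tables for a given dt.  Assembled from
# the session cache (keyed by parameter set, quantized temperature and dt) so
# coupled runs that update the temperature field every chunk pay the
# exponential tabulation once per temperature level.  Exact [[ ]] indexing
# avoids partial matching against "explut_dt".
tissue_explut <- function(state, dt) {
  if (!is.null(state[["explut"]]) && identical(state[["explut_dt"]], dt))
    return(state)
  gl <- gate_lut(state$params)
  pk <- params_key(state$params)
  one <- function(k) {
    key <- sprintf("exp:%s:%.1f:%g", pk, state$group_temps[k], dt)
    e <- .cryo_cache[[key]]
    if (is.null(e)) {
      e <- build_exp_lut_cpp(gl, state$group_scalers[, k], dt)
      .cryo_cache[[key]] <- e
    }
    e
  }
  state[["explut"]] <- do.call(cbind,
    lapply(seq_len(ncol(state$group_scalers)), one))
  state[["explut_dt"]] <- dt
  state
}

#' Extrude a 2D tissue state into a thin 3D slab
#'
#' Replicates a 2D monodomain state across `nz` identical layers, producing
#' a scroll wave whose filament is initially straight and transmural when
#' the source state carries a spiral.
#'
#' @param state a 2D [tissue_state()].
#' @param nz number of layers (>= 3).
#' @return a 3D `tissue_state` of shape `c(nx, ny, nz)`.
#' @export
extrude_state <- function(state, nz = 4L) {
  g <- state$geometry
  stopifnot(g$ndim == 2, nz >= 3)
  g3 <- tissue_geometry(c(g$shape, as.integer(nz)), g$dx)
  st3 <- state
  st3$geometry <- g3
  st3$S <- state$S[, rep(seq_len(g$N), nz), drop = FALSE]
  st3 <- set_temperature(st3, rep(state$temp, nz))
  st3
}

#' Discrete Laplacian with zero-flux boundaries
#'
#' Centered second-order stencil with mirror boundaries on every side, the
#' spatial operator of the monodomain equation.
#'
#' @param V numeric vector (1D), matrix (2D) or 3D array.
#' @param dx grid spacing (cm).
#' @return Laplacian of `V`, same shape (1/cm^2 units times V's units).
#' @export
laplacian <- function(V, dx = 0.03) {
  d <- dim(V)
  if (is.null(d)) d <- length(V)
  shape <- as.integer(d)
  nb <- build_neighbors(shape)
  v <- as.numeric(V)
  acc <- -2 * length(shape) * v
  for (k in seq_len(nrow(nb))) acc <- acc + v[nb[k, ] + 1L]
  out <- acc / dx^2
  if (length(shape) > 1) dim(out) <- shape
  out
}

# stimulus helper: 0-based node indices of a rectangular region (grid units)
region_nodes <- function(geometry, xlim = NULL, ylim = NULL, zlim = NULL) {
  sh <- geometry$shape
  idx <- arrayInd(seq_len(geometry$N), sh)
  keep <- rep(TRUE, geometry$N)
  lims <- list(xlim, ylim, zlim)
  for (a in seq_len(geometry$ndim)) {
    if (!is.null(lims[[a]]))
      keep <- keep & idx[, a] >= lims[[a]][1] & idx[, a] <= lims[[a]][2]
  }
  which(keep) - 1L
}

#' Advance a tissue state
#'
#' Forward-Euler monodomain stepping: every node advances with its local
#' temperature's kinetics scalers, the centered-difference Laplacian couples
#' neighbors with zero-flux boundaries, and stimulus currents are applied to
#' the listed node sets.  The explicit stability bound `D dt/dx^2 <= 1/(2 d)`
#' is checked.
#'
#' @param state a [tissue_state()].
#' @param duration simulated time (ms).
#' @param dt time step (ms), <= 0.02.
#' @param stims list of stimuli: each `list(nodes = <0-based ints>,
#'   start = ms, dur = ms, amp = pA/pF)` with `start` in absolute simulated
#'   time.
#' @param snap_every snapshot cadence (ms); 0 disables snapshots.
#' @return list with the advanced `state`, `snapshots` (matrix, one row per
#'   frame), `times` (ms) and `clamps`.  Numerical blow-up aborts with the
#'   time and node location.
#' @export
run_tissue <- function(state, duration, dt = 0.02, stims = list(),
                       snap_every = 10, nernst_every = 1L) {
  g <- state$geometry
  if (dt > 0.02 + 1e-12) stop("dt must be <= 0.02 ms", call. = FALSE)
  cfl <- state$D * dt / g$dx^2
  if (cfl > 1 / (2 * g$ndim))
    stop(sprintf("unstable configuration: D dt/dx^2 = %.3f > %.3f",
                 cfl, 1 / (2 * g$ndim)), call. = FALSE)
  state <- tissue_explut(state, dt)
  nb <- build_neighbors(g$shape)
  nsteps <- ceiling(duration / dt)
  snap_steps <- if (snap_every > 0) max(1L, round(snap_every / dt)) else 0L
  S <- state$S  # tissue_run_cpp advances the matrix in place on a copy
  S2 <- S + 0
  res <- tissue_run_cpp(S2, nb, gate_lut(state$params), state$thermo,
                        state[["explut"]], state$rtf, state$groups,
                        state$scalers,
                        kernel_params(state$params), state$D, g$dx, dt,
                        state$t, nsteps, stims, snap_steps,
                        as.integer(nernst_every))
  if (res$status != "ok")
    stop(sprintf("tissue run unstable at t = %.2f ms (node %d)",
                 res$t, res$node), call. = FALSE)
  state$S <- S2
  state$t <- state$t + nsteps * dt
  ns <- res$nsnap
  list(state = state,
       snapshots = if (ns > 0) res$snapshots[seq_len(ns), , drop = FALSE],
       times = if (ns > 0) res$snap_t[seq_len(ns)],
       clamps = res$clamps)
}

#' Planar conduction velocity in a 1D cable
#'
#' Stimulates one end of a uniform cable and measures the activation-time
#' difference (maximal dV/dt crossing) between two sensing nodes placed at
#' least 1.5 cm apart and 1 cm away from either end, avoiding stimulus and
#' boundary artifacts.
#'
#' @param params a `crn_params`.
#' @param T uniform temperature (degC).
#' @param D diffusion constant (cm^2/ms).
#' @param dx spatial step (cm).
#' @param cable_cm cable length (cm), default 6.
#' @param dt time step (ms).
#' @param q10s a `q10_set`.
#' @return conduction velocity (cm/s) with attribute `activation_times`.
#' @export
measure_cv <- function(params, T = 37, D = 0.0025, dx = 0.03, cable_cm = 6,
                       dt = 0.02, q10s = q10_set()) {
  n <- round(cable_cm / dx) + 1L
  g <- tissue_geometry(n, dx)
  st <- tissue_state(g, params, T = T, D = D, q10s = q10s)
  amp <- 2 * find_threshold(params, T, q10s = q10s)
  # stimulated end segment wide enough to overcome the diffusive sink
  stim <- list(nodes = region_nodes(g, xlim = c(1, round(0.45 / dx) + 1)),
               start = 1, dur = 2, amp = amp)
  # sensing nodes: >= 1 cm from the ends, >= 1.5 cm apart
  i1 <- round(1.5 / dx) + 1L
  i2 <- round((cable_cm - 1.5) / dx) + 1L
  # conduction slows at cold; allow generous horizon
  horizon <- if (T >= 25) 150 else 600
  r <- run_tissue(st, horizon, dt = dt, stims = list(stim), snap_every = 0.1)
  act <- function(i) {
    v <- r$snapshots[, i]
    tt <- r$times
    k <- which.max(diff(v) / diff(tt))
    (tt[k] + tt[k + 1]) / 2
  }
  t1 <- act(i1); t2 <- act(i2)
  if (t2 <= t1) stop("no propagating wave reached the distal sensor")
  cv <- (i2 - i1) * dx / (t2 - t1) * 1000  # cm/s
  attr(cv, "activation_times") <- c(t1 = t1, t2 = t2)
  cv
}

#' Induce a reentrant wave by the S1-S2 cross-field protocol
#'
#' S1 launches a planar wave from the low-x edge; S2 is a half-domain
#' (quarter-domain in 3D) block applied orthogonally, timed on the
#' repolarization tail of S1.  If `s2_time` is `NULL`, candidate times are
#' scanned (coarse-to-fine) and the first that leaves a persistent
#' phase singularity after `verify_ms` is kept.
#'
#' @param state a resting [tissue_state()] (2D or 3D).
#' @param s2_time absolute S2 onset (ms) or `NULL` to scan.
#' @param scan_range window (ms) scanned for the S2 onset.
#' @param scan_step scan resolution (ms).
#' @param verify_ms continuation time used to verify a sustained spiral.
#' @param stim_amp stimulus amplitude (pA/pF); default 2x threshold.
#' @param snap_every snapshot cadence (ms).
#' @return list: advanced `state` containing the reentry, `s2_time`,
#'   `snapshots`, `times`, and `tips` (trajectory over the verification
#'   window).  Fails with a protocol-failure error when no scanned S2 yields
#'   reentry.
#' @export
run_s1s2 <- function(state, s2_time = NULL, scan_range = NULL, scan_step = 10,
                     verify_ms = 400, stim_amp = NULL, snap_every = 10) {
  g <- state$geometry
  stopifnot(g$ndim >= 2)
  if (is.null(stim_amp))
    stim_amp <- 2 * find_threshold(state$params, round(median(state$temp), 1),
                                   q10s = state$q10s)
  s1_nodes <- region_nodes(g, xlim = c(1, max(3, round(0.15 / g$dx) + 1)))
  ny <- g$shape[2]
  s2_lims <- list(xlim = c(1, g$shape[1]), ylim = c(1, floor(ny / 2)))
  if (g$ndim == 3)
    s2_lims$xlim <- c(1, floor(g$shape[1] / 2))
  s2_nodes <- do.call(region_nodes, c(list(g), s2_lims))
  track_mid <- function(snaps, tms) {
    if (g$ndim == 2)
      track_tips(snaps, tms, g$shape[1], g$shape[2], g$dx)
    else {
      nz <- g$shape[3]
      lay <- region_nodes(g, zlim = c(ceiling(nz / 2), ceiling(nz / 2))) + 1L
      track_tips(snaps[, lay, drop = FALSE], tms, g$shape[1], g$shape[2],
                 g$dx)
    }
  }
  if (!is.null(s2_time)) cand <- s2_time
  else {
    if (is.null(scan_range)) {
      a90 <- ap_metrics(run_cell(state$params,
                                 round(median(state$temp), 1),
                                 duration = 2000, stim_times = 10,
                                 q10s = state$q10s)$trace,
                        stim_times = 10)$apd[["APD90"]]
      cand <- seq(max(20, a90 * 0.6), a90 * 1.6, by = scan_step)
    } else cand <- seq(scan_range[1], scan_range[2], by = scan_step)
  }
  # advance the S1 trajectory once, branching an S2 attempt at each candidate
  t0 <- state$t
  base <- run_tissue(state, cand[1] - t0,
                     stims = list(list(nodes = s1_nodes, start = t0 + 1,
                                       dur = 2, amp = stim_amp)),
                     snap_every = 0)$state
  for (k in seq_along(cand)) {
    s2t <- cand[k]
    branch <- base
    r <- run_tissue(branch, 2 + verify_ms,
                    stims = list(list(nodes = s2_nodes, start = s2t, dur = 2,
                                      amp = stim_amp)),
                    snap_every = snap_every)
    tips <- track_mid(r$snapshots, r$times)
    last <- utils::tail(tips, 5)
    if (nrow(last) > 0 && all(last$n_tips > 0))
      return(list(state = r$state, s2_time = s2t, snapshots = r$snapshots,
                  times = r$times, tips = tips))
    if (k < length(cand))
      base <- run_tissue(base, cand[k + 1] - s2t, snap_every = 0)$state
  }
  stop("S1-S2 protocol failure: no scanned S2 onset (",
       paste(range(cand), collapse = "-"),
       " ms) produced sustained reentry", call. = FALSE)
}

#' Coupled electrophysiology + bioheat run
#'
#' Advances the monodomain EP state and the bioheat temperature field
#' together: the heat equation is stepped over each coupling interval
#' (sub-cycled internally at its own stable step) and the resulting field is
#' held piecewise-constant for the EP steps of that interval.  With all
#' sources at body temperature the trajectory coincides with an uncoupled
#' EP run.
#'
#' @param state a [tissue_state()] (the EP grid).
#' @param field a [temperature_field()] co-located with the EP grid.
#' @param props a [thermal_properties()].
#' @param spots list of [cold_spot()]s (activation windows in seconds).
#' @param duration simulated EP time (ms).
#' @param heat_every_ms coupling interval (ms).
#' @param dt EP time step (ms).
#' @param snap_every snapshot cadence (ms).
#' @param stims stimulus list as in [run_tissue()].
#' @return list with advanced `state`, `field`, concatenated `snapshots` and
#'   `times`.
#' @export
coupled_run <- function(state, field, props = thermal_properties(),
                        spots = list(), duration, heat_every_ms = 50,
                        dt = 0.02, snap_every = 10, stims = list()) {
  stopifnot(all(field$shape == state$geometry$shape))
  if (abs(heat_every_ms / dt - round(heat_every_ms / dt)) > 1e-9)
    stop("heat_every_ms must be an integer multiple of dt", call. = FALSE)
  snaps <- NULL; times <- NULL
  t_done <- 0
  while (t_done < duration - 1e-9) {
    h <- min(heat_every_ms, duration - t_done)
    field <- run_heat(field, props, spots, h / 1000, t0 = state$t / 1000)
    state <- set_temperature(state, as.numeric(field$T))
    r <- run_tissue(state, h, dt = dt, stims = stims,
                    snap_every = snap_every, nernst_every = 5L)
    state <- r$state
    if (!is.null(r$snapshots)) {
      snaps <- rbind(snaps, r$snapshots)
      times <- c(times, r$times)
    }
    t_done <- t_done + h
  }
  list(state = state, field = field, snapshots = snaps, times = times)
}
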