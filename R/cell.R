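# Single-cell interface: state construction, current computation, stepping,
# stimulation and equilibration.

STATE_NAMES <- c("V", "m", "h", "j", "oa", "oi", "ua", "ui", "xr", "xs",
                 "d", "f", "f_Ca", "u", "v", "w",
                 "Na_i", "K_i", "Ca_i", "Ca_up", "Ca_rel")
GATE_NAMES <- STATE_NAMES[2:16]
CONC_NAMES <- STATE_NAMES[17:21]
CURRENT_NAMES <- c("INa", "IK1", "Ito", "IKur", "IKr", "IKs", "IBNa", "IBCa",
                   "INaK", "ICaP", "INaCa", "ICaL")

# package-level caches (gate/thermo LUTs, equilibrated states, thresholds)
.cryo_cache <- new.env(parent = emptyenv())

#' CRN cell state vector
#'
#' Constructs the 21-component state of one atrial cell: membrane potential
#' `V` (mV), the 15 CRN gating variables (dimensionless, in \[0,1\]) and the 5
#' intracellular concentrations (mM).  Defaults are the published CRN resting
#' initial conditions at 37 degC.
#'
#' @param V membrane potential (mV).
#' @param gates named numeric vector of the 15 gating variables.
#' @param concentrations named numeric vector `Na_i, K_i, Ca_i, Ca_up, Ca_rel`.
#' @return named numeric vector of class `cell_state`.
#' @export
cell_state <- function(V = -81.18,
                       gates = c(m = 2.908e-3, h = 0.9649, j = 0.9775,
                                 oa = 3.043e-2, oi = 0.9992, ua = 4.966e-3,
                                 ui = 0.9986, xr = 3.296e-5, xs = 1.869e-2,
                                 d = 1.367e-4, f = 0.9996, f_Ca = 0.7755,
                                 u = 0, v = 1, w = 0.9992),
                       concentrations = c(Na_i = 11.17, K_i = 139.0,
                                          Ca_i = 1.013e-4, Ca_up = 1.488,
                                          Ca_rel = 1.488)) {
  s <- c(V = V, gates[GATE_NAMES], concentrations[CONC_NAMES])
  names(s) <- STATE_NAMES
  validate_cell_state(s)
}

#' Validate a cell state against its invariants
#'
#' Gates in \[0,1\], concentrations positive, `V` finite in \[-120, 80\] mV.
#' @param s a state vector as built by [cell_state()].
#' @return the state, invisibly usable; errors name the offending variable.
#' @export
validate_cell_state <- function(s) {
  if (length(s) != 21) stop("cell state must have 21 components")
  names(s) <- STATE_NAMES
  bad <- STATE_NAMES[!is.finite(s)]
  if (length(bad))
    stop("non-finite state variable: ", paste(bad, collapse = ", "),
         call. = FALSE)
  if (!is.finite(s[["V"]]) || s[["V"]] < -120 || s[["V"]] > 80)
    stop("V outside [-120, 80] mV: ", s[["V"]], call. = FALSE)
  g <- s[GATE_NAMES]
  if (any(g < 0 | g > 1))
    stop("gate outside [0,1]: ",
         paste(GATE_NAMES[g < 0 | g > 1], collapse = ", "), call. = FALSE)
  cc <- s[CONC_NAMES]
  if (any(cc <= 0))
    stop("non-positive concentration: ",
         paste(CONC_NAMES[cc <= 0], collapse = ", "), call. = FALSE)
  structure(s, class = "cell_state")
}

# ---- LUT management -------------------------------------------------------

LUT_VMIN <- -120
LUT_VMAX <- 80
LUT_DV <- 0.05

params_key <- function(params) {
  paste(c(params$conductances, params$kinetic_shifts, params$tau_scales),
        collapse = ",")
}

gate_lut <- function(params) {
  key <- paste0("gate:", params_key(params))
  lut <- .cryo_cache[[key]]
  if (is.null(lut)) {
    lut <- build_gate_lut_cpp(params$kinetic_shifts[c("h", "oa", "d")],
                              params$tau_scales[["d"]],
                              LUT_VMIN, LUT_VMAX, LUT_DV)
    .cryo_cache[[key]] <- lut
  }
  lut
}

# thermo LUT cached per temperature quantized to 0.1 degC
thermo_lut <- function(T) {
  Tq <- round(T, 1)
  key <- sprintf("thermo:%.1f", Tq)
  lut <- .cryo_cache[[key]]
  if (is.null(lut)) {
    lut <- build_thermo_lut_cpp(Tq, LUT_VMIN, LUT_VMAX, LUT_DV)
    .cryo_cache[[key]] <- lut
  }
  lut
}

#' @keywords internal
clear_cryo_cache <- function() {
  rm(list = ls(.cryo_cache), envir = .cryo_cache)
  invisible(NULL)
}

# ---- currents (reference R implementation, independent of the LUT path) ---

#' Compute the 12 membrane currents at a given state
#'
#' Direct (table-free) evaluation of all CRN membrane currents at one cell
#' state and temperature, in pA/pF.  Conductances come from `params`;
#' temperature enters through the thermodynamic factor RT/F in the Nernst
#' potentials and in the Na/K-pump and Na/Ca-exchanger voltage dependence.
#' This is the package's reference formulation: the optimized lookup-table
#' kernel is tested against it.
#'
#' @param state a [cell_state()] vector.
#' @param params a `crn_params` object.
#' @param T temperature (degC).
#' @return named list with the 12 currents
#'   (`INa, IK1, Ito, IKur, IKr, IKs, IBNa, IBCa, INaK, ICaP, INaCa, ICaL`)
#'   and their sum `Iion`.
#' @export
compute_currents <- function(state, params, T = 37) {
  s <- validate_cell_state(state)
  validate_params(params)
  g <- params$conductances
  V <- s[["V"]]; Nai <- s[["Na_i"]]; Ki <- s[["K_i"]]; Cai <- s[["Ca_i"]]
  rtf <- 8.3143 * (273.15 + T) / 96.4867
  ENa <- rtf * log(140 / Nai)
  EK <- rtf * log(5.4 / Ki)
  ECa <- rtf / 2 * log(1.8 / Cai)
  sigma <- (exp(140 / 67.3) - 1) / 7
  fnak <- 1 / (1 + 0.1245 * exp(-0.1 * V / rtf) +
                 0.0365 * sigma * exp(-V / rtf))
  eg <- exp(0.35 * V / rtf); eg1 <- exp(-0.65 * V / rtf)
  cur <- list(
    INa = g[["g_Na"]] * s[["m"]]^3 * s[["h"]] * s[["j"]] * (V - ENa),
    IK1 = g[["g_K1"]] * (V - EK) / (1 + exp(0.07 * (V + 80))),
    Ito = g[["g_to"]] * s[["oa"]]^3 * s[["oi"]] * (V - EK),
    IKur = (0.005 + 0.05 / (1 + exp(-(V - 15) / 13))) *
      s[["ua"]]^3 * s[["ui"]] * (V - EK),
    IKr = g[["g_Kr"]] * s[["xr"]] * (V - EK) / (1 + exp((V + 15) / 22.4)),
    IKs = g[["g_Ks"]] * s[["xs"]]^2 * (V - EK),
    IBNa = g[["g_bNa"]] * (V - ENa),
    IBCa = g[["g_bCa"]] * (V - ECa),
    INaK = g[["i_NaK_max"]] * fnak * (5.4 / (5.4 + 1.5)) /
      (1 + (10 / Nai)^1.5),
    ICaP = g[["i_pCa_max"]] * Cai / (0.0005 + Cai),
    INaCa = g[["i_NaCa_max"]] *
      (eg * Nai^3 * 1.8 - eg1 * 140^3 * Cai) /
      ((87.5^3 + 140^3) * (1.38 + 1.8) * (1 + 0.1 * eg1)),
    ICaL = g[["g_CaL"]] * s[["d"]] * s[["f"]] * s[["f_Ca"]] * (V - 65)
  )
  cur$Iion <- sum(unlist(cur))
  cur
}

# ---- stepping and runs ----------------------------------------------------

run_args <- function(params, q10s, T) {
  list(lut = gate_lut(params), thermo = thermo_lut(T),
       scalers = kernel_scalers(params, q10s, T),
       kp = kernel_params(params))
}

#' Advance a single cell by one (or more) explicit Euler steps
#'
#' @param state a [cell_state()] vector.
#' @param params a `crn_params` object.
#' @param T temperature (degC).
#' @param Istim stimulus current (pA/pF); negative values depolarize.
#' @param dt time step (ms), must not exceed 0.02.
#' @param n number of steps (default 1).
#' @param q10s a `q10_set`.
#' @return the advanced `cell_state`.
#' @export
step_cell <- function(state, params, T = 37, Istim = 0, dt = 0.02, n = 1,
                      q10s = q10_set()) {
  s <- validate_cell_state(state)
  if (dt > 0.02 + 1e-12)
    stop("dt must be <= 0.02 ms for the explicit scheme", call. = FALSE)
  a <- run_args(params, q10s, T)
  res <- cell_run_cpp(as.numeric(s), a$lut, a$thermo, a$scalers, a$kp,
                      dt, 0, n, if (Istim != 0) 0 else numeric(0),
                      n * dt, Istim, 0L)
  if (res$status != "ok")
    stop("cell state blew up (|V| > 200 mV) at t = ", res$t,
         " ms; use a smaller dt", call. = FALSE)
  out <- res$state
  names(out) <- STATE_NAMES
  structure(out, class = "cell_state")
}

#' Run a single cell and record its voltage trace
#'
#' Forward-Euler integration of one cell at fixed temperature, with optional
#' rectangular stimulus pulses.  By default the run starts from the
#' equilibrated resting state at `T` (see [equilibrate()]) and the stimulus
#' amplitude is twice the diastolic threshold found by bisection.
#'
#' @param params a `crn_params` object.
#' @param T temperature (degC).
#' @param duration simulated time (ms).
#' @param dt time step (ms), <= 0.02.
#' @param stim_times onsets (ms) of the stimulus pulses; `numeric(0)` for an
#'   unstimulated run.
#' @param stim_dur pulse duration (ms), default 2.
#' @param stim_amp pulse amplitude (pA/pF, negative = depolarizing); `NULL`
#'   uses twice the diastolic threshold.
#' @param state0 initial state; `NULL` uses the cached equilibrated state.
#' @param record_every sampling interval in steps (default: every 0.5 ms).
#' @param record_currents if `TRUE` the trace also carries the 12 currents.
#' @param q10s a `q10_set`.
#' @return list with `trace` (data.frame: `t`, `V`, `Ca_i`, and the currents
#'   when requested), the final `state`, the gate-clamp event count `clamps`
#'   and the stimulus amplitude used.
#' @export
run_cell <- function(params, T = 37, duration = 1000, dt = 0.02,
                     stim_times = 0, stim_dur = 2, stim_amp = NULL,
                     state0 = NULL, record_every = NULL,
                     record_currents = FALSE, q10s = q10_set()) {
  validate_params(params)
  if (dt > 0.02 + 1e-12)
    stop("dt must be <= 0.02 ms for the explicit scheme", call. = FALSE)
  if (is.null(state0)) state0 <- equilibrate(params, T, q10s = q10s)$state
  if (is.null(stim_amp) && length(stim_times))
    stim_amp <- 2 * find_threshold(params, T, q10s = q10s)
  if (is.null(stim_amp)) stim_amp <- 0
  if (is.null(record_every)) record_every <- max(1L, round(0.5 / dt))
  a <- run_args(params, q10s, T)
  nsteps <- ceiling(duration / dt)
  if (record_currents) {
    res <- cell_run_currents_cpp(as.numeric(state0), a$lut, a$thermo,
                                 a$scalers, a$kp, dt, nsteps,
                                 as.numeric(stim_times), stim_dur, stim_amp,
                                 as.integer(record_every))
    tr <- as.data.frame(res$trace[seq_len(res$nrec), , drop = FALSE])
    names(tr) <- c("t", "V", "Ca_i", CURRENT_NAMES)
  } else {
    res <- cell_run_cpp(as.numeric(state0), a$lut, a$thermo, a$scalers, a$kp,
                        dt, 0, nsteps, as.numeric(stim_times), stim_dur,
                        stim_amp, as.integer(record_every))
    if (res$status != "ok")
      stop("cell run unstable at t = ", res$t, " ms; use a smaller dt",
           call. = FALSE)
    tr <- as.data.frame(res$trace[seq_len(res$nrec), , drop = FALSE])
    names(tr) <- c("t", "V", "Ca_i")
  }
  st <- res$state
  names(st) <- STATE_NAMES
  list(trace = tr, state = structure(st, class = "cell_state"),
       clamps = res$clamps, stim_amp = stim_amp)
}

#' Equilibrate a cell at fixed temperature
#'
#' Runs the unstimulated cell from the CRN initial conditions until the
#' membrane potential drift over the final second falls below
#' `drift_tol` (mV/s).  Results are cached per (parameter set, temperature,
#' duration) within the session.
#'
#' @param params a `crn_params` object.
#' @param T temperature (degC).
#' @param duration simulated equilibration time in seconds (default 60).
#' @param dt time step (ms).
#' @param drift_tol admissible residual drift (mV/s), default 1e-3.
#' @param q10s a `q10_set`.
#' @return list with the resting `state`, the measured `drift` (mV/s) and
#'   `converged` (logical).  A run that fails the drift criterion warns and
#'   reports the residual drift.
#' @export
equilibrate <- function(params, T = 37, duration = 60, dt = 0.02,
                        drift_tol = 1e-3, q10s = q10_set()) {
  validate_params(params)
  key <- sprintf("eq:%s:%.1f:%g:%g", params_key(params), round(T, 1),
                 duration, dt)
  hit <- .cryo_cache[[key]]
  if (!is.null(hit)) return(hit)
  a <- run_args(params, q10s, T)
  nsteps <- ceiling(duration * 1000 / dt)
  res <- cell_run_cpp(as.numeric(cell_state()), a$lut, a$thermo, a$scalers,
                      a$kp, dt, 0, nsteps, numeric(0), 0, 0,
                      as.integer(round(1000 / dt)))  # sample every 1 s
  if (res$status != "ok")
    stop("equilibration unstable at t = ", res$t, " ms", call. = FALSE)
  tr <- res$trace[seq_len(res$nrec), , drop = FALSE]
  drift <- abs(diff(tail(tr[, 2], 2))) / (diff(tail(tr[, 1], 2)) / 1000)
  st <- res$state
  names(st) <- STATE_NAMES
  out <- list(state = structure(st, class = "cell_state"),
              drift = drift, converged = drift < drift_tol)
  if (!out$converged)
    warning(sprintf(
      "equilibration at %.1f degC did not converge: residual drift %.2g mV/s",
      T, drift))
  .cryo_cache[[key]] <- out
  out
}

#' Diastolic stimulation threshold by bisection
#'
#' Finds the minimal amplitude of a 2-ms rectangular pulse that elicits an
#' action potential (peak V above 0 mV) from the equilibrated resting state,
#' by bisection on the amplitude magnitude.
#'
#' @inheritParams run_cell
#' @param tol bisection tolerance (pA/pF).
#' @return the threshold amplitude (negative, pA/pF), cached per
#'   (parameter set, temperature).
#' @export
find_threshold <- function(params, T = 37, stim_dur = 2, tol = 0.25,
                           q10s = q10_set()) {
  key <- sprintf("thr:%s:%.1f", params_key(params), round(T, 1))
  hit <- .cryo_cache[[key]]
  if (!is.null(hit)) return(hit)
  st0 <- equilibrate(params, T, q10s = q10s)$state
  a <- run_args(params, q10s, T)
  # observation long enough to capture a slow cold upstroke
  obs <- if (T < 20) 2000 else 400
  fires <- function(amp) {
    res <- cell_run_cpp(as.numeric(st0), a$lut, a$thermo, a$scalers, a$kp,
                        0.02, 0, ceiling(obs / 0.02), 0, stim_dur, -amp,
                        as.integer(50))
    if (res$status != "ok") return(TRUE)
    max(res$trace[seq_len(res$nrec), 2]) > 0
  }
  lo <- 0; hi <- 4
  while (!fires(hi) && hi < 256) hi <- hi * 2
  if (hi >= 256) stop("no capture up to 256 pA/pF", call. = FALSE)
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (fires(mid)) hi <- mid else lo <- mid
  }
  .cryo_cache[[key]] <- -hi
  -hi
}
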