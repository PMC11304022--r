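# Bioheat conduction: explicit diffusion of the tissue temperature field with
# cold-spot Dirichlet sources.  Horizontal faces (first/last layer along the
# last axis) are held at body temperature except inside an active spot;
# vertical faces are zero-flux.  The solver works in seconds and degC with
# SI thermal properties; grid spacings are given in cm and converted.

#' Thermal properties of cardiac tissue
#'
#' @param rho density (kg/m^3), default 1050.
#' @param C specific heat capacity (J/(kg K)), default 4219.
#' @param kt thermal conductivity (W/(m K)), default 0.7.
#' @return object of class `thermal_properties` with the derived diffusivity
#'   `kappa` (m^2/s) and `kappa_cm2s` (cm^2/s).
#' @export
thermal_properties <- function(rho = 1050, C = 4219, kt = 0.7) {
  stopifnot(rho > 0, C > 0, kt > 0)
  kappa <- kt / (rho * C)
  if (!is.finite(kappa)) stop("non-finite thermal diffusivity")
  structure(list(rho = rho, C = C, kt = kt, kappa = kappa,
                 kappa_cm2s = kappa * 1e4),
            class = "thermal_properties")
}

#' Temperature field on a regular grid
#'
#' @param shape integer vector of node counts (1, 2 or 3 axes); the last axis
#'   is transmural (its first/last layers are the horizontal faces).
#' @param spacing grid spacing per axis (cm), recycled.
#' @param T initial temperature (degC), scalar or array of dim `shape`.
#' @return object of class `temperature_field`: list with the temperature
#'   array `T`, `shape`, `spacing` (cm) and `body_T`.
#' @export
temperature_field <- function(shape, spacing = 0.03, T = 37, body_T = 37) {
  shape <- as.integer(shape)
  stopifnot(length(shape) %in% 1:3, all(shape >= 3), all(spacing > 0))
  spacing <- rep_len(spacing, length(shape))
  arr <- array(T, dim = shape)
  structure(list(T = arr, shape = shape, spacing = spacing, body_T = body_T),
            class = "temperature_field")
}

#' Cold-spot Dirichlet source
#'
#' A circular region of fixed low (non-freezing) temperature imposed on one
#' horizontal face of the slab; depth penetration is purely by conduction.
#'
#' @param center lateral center coordinates (cm); one value per lateral axis.
#' @param radius spot radius (cm), default 0.9 (the 9-mm spot).
#' @param T_spot spot temperature (degC), default 5; must lie in \[0, 37\].
#' @param face `"top"` (last transmural layer) or `"bottom"` (first).
#' @param t_on,t_off activation window (s).
#' @return object of class `cold_spot`.
#' @export
cold_spot <- function(center, radius = 0.9, T_spot = 5,
                      face = c("top", "bottom"), t_on = 0, t_off = Inf) {
  face <- match.arg(face)
  stopifnot(radius > 0, T_spot >= 0, T_spot <= 37, t_off > t_on)
  structure(list(center = center, radius = radius, T_spot = T_spot,
                 face = face, t_on = t_on, t_off = t_off),
            class = "cold_spot")
}

# neighbor table with mirror boundaries: 2*ndim x N, 0-based for C++
build_neighbors <- function(shape) {
  nd <- length(shape)
  N <- prod(shape)
  idx <- arrayInd(seq_len(N), shape)
  nb <- matrix(0L, 2L * nd, N)
  # zero-flux closure by half-point mirror (ghost = boundary value), the
  # conservative choice: the domain integral of the Laplacian vanishes
  for (a in seq_len(nd)) {
    up <- idx
    up[, a] <- pmin(idx[, a] + 1L, shape[a])
    dn <- idx
    dn[, a] <- pmax(idx[, a] - 1L, 1L)
    lin <- function(m) {
      l <- m[, 1]
      if (nd > 1) for (b in 2:nd) l <- l + (m[, b] - 1L) * prod(shape[1:(b - 1)])
      l
    }
    nb[2L * a - 1L, ] <- lin(dn) - 1L
    nb[2L * a, ] <- lin(up) - 1L
  }
  nb
}

# lateral node mask of a spot footprint (matrix/vector over the lateral axes)
spot_footprint <- function(field, spot) {
  sh <- field$shape
  nd <- length(sh)
  if (nd == 1) stop("a 1D field has no lateral extent for a spot")
  lat <- sh[-nd]
  sp <- field$spacing[-nd]
  co <- lapply(seq_along(lat), function(a) ((seq_len(lat[a])) - 1) * sp[a])
  if (length(lat) == 1) {
    abs(co[[1]] - spot$center[1]) <= spot$radius
  } else {
    outer(co[[1]] - spot$center[1], co[[2]] - spot$center[2],
          function(a, b) sqrt(a^2 + b^2)) <= spot$radius
  }
}

# Dirichlet node set (0-based indices + values) for the BCs at time t (s)
dirichlet_set <- function(field, spots, t = 0) {
  sh <- field$shape
  nd <- length(sh)
  N <- prod(sh)
  face_mask <- array(FALSE, sh)
  if (nd == 1) {
    face_mask[c(1, sh[1])] <- TRUE
  } else if (nd == 2) {
    face_mask[, c(1, sh[2])] <- TRUE
  } else {
    face_mask[, , c(1, sh[3])] <- TRUE
  }
  vals <- array(NA_real_, sh)
  vals[face_mask] <- field$body_T
  for (sp in spots) {
    if (t < sp$t_on || t >= sp$t_off) next
    fp <- spot_footprint(field, sp)
    layer <- if (sp$face == "top") sh[nd] else 1L
    if (nd == 2) {
      v <- vals[, layer]; v[fp] <- sp$T_spot; vals[, layer] <- v
    } else {
      v <- vals[, , layer]; v[fp] <- sp$T_spot; vals[, , layer] <- v
    }
  }
  keep <- which(!is.na(vals))
  list(idx = keep - 1L, val = vals[keep])
}

#' Explicit stability bound for the heat step
#'
#' @param field a [temperature_field()].
#' @param props a [thermal_properties()].
#' @return the maximal stable `dt_heat` (s) of the explicit scheme,
#'   `1 / (2 kappa sum(1/h_a^2))`.
#' @export
heat_dt_max <- function(field, props) {
  h <- field$spacing / 100  # m
  1 / (2 * props$kappa * sum(1 / h^2))
}

#' Advance the temperature field
#'
#' Explicit centered-difference diffusion with Dirichlet values (body
#' temperature on the horizontal faces, spot interiors) re-imposed after
#' every step, preserving the discrete maximum principle.
#'
#' @param field a [temperature_field()].
#' @param props a [thermal_properties()].
#' @param spots list of [cold_spot()]s (or a single one).
#' @param duration simulated time (s).
#' @param dt_heat step (s); default 90% of the stability bound.  A value
#'   above the bound is a configuration error reporting the bound.
#' @param t0 current time (s), used to evaluate spot activation windows.
#' @return the field advanced by `duration`.
#' @export
run_heat <- function(field, props, spots = list(), duration,
                     dt_heat = NULL, t0 = 0) {
  if (inherits(spots, "cold_spot")) spots <- list(spots)
  dmax <- heat_dt_max(field, props)
  if (is.null(dt_heat)) dt_heat <- 0.9 * dmax
  if (dt_heat > dmax * (1 + 1e-9))
    stop(sprintf("dt_heat %.4g s exceeds the stability bound %.4g s",
                 dt_heat, dmax), call. = FALSE)
  nsteps <- max(1L, round(duration / dt_heat))
  # split at spot on/off events inside the window
  ev <- sort(unique(unlist(lapply(spots, function(s) c(s$t_on, s$t_off)))))
  ev <- ev[ev > t0 & ev < t0 + duration]
  bounds <- c(t0, ev, t0 + duration)
  nb <- build_neighbors(field$shape)
  h <- field$spacing / 100
  Tvec <- as.numeric(field$T)
  for (k in seq_len(length(bounds) - 1)) {
    seg <- bounds[k + 1] - bounds[k]
    ns <- max(1L, round(seg / dt_heat))
    w <- props$kappa * (seg / ns) / h^2
    ds <- dirichlet_set(field, spots, bounds[k])
    # impose Dirichlet before stepping so sources act from t_on
    Tvec[ds$idx + 1L] <- ds$val
    Tvec <- heat_run_cpp(Tvec, nb, w, ds$idx, ds$val, ns)
  }
  field$T <- array(Tvec, field$shape)
  field
}

#' @rdname run_heat
#' @param n number of steps for [step_heat()] (default 1).
#' @export
step_heat <- function(field, props, spots = list(), dt_heat, n = 1) {
  run_heat(field, props, spots, duration = n * dt_heat, dt_heat = dt_heat)
}

#' Steady-state temperature field
#'
#' Runs the configuration to convergence (max per-chunk change below `tol`).
#'
#' @inheritParams run_heat
#' @param tol convergence tolerance (degC per chunk), default 1e-3.
#' @param chunk chunk duration (s), default 5.
#' @param max_time bail-out horizon (s).
#' @return the converged field.
#' @export
steady_state_heat <- function(field, props, spots = list(), tol = 1e-3,
                              chunk = 5, max_time = 2000) {
  t <- 0
  repeat {
    prev <- field$T
    field <- run_heat(field, props, spots, chunk, t0 = t)
    t <- t + chunk
    if (max(abs(field$T - prev)) < tol) return(field)
    if (t > max_time)
      stop("steady state not reached within ", max_time, " s", call. = FALSE)
  }
}

#' Time to establish a transmural cold column
#'
#' Simulates a cold spot applied at `t = 0` to one face of a slab initially
#' at body temperature and returns the first time at which the whole
#' transmural column of free (non-Dirichlet) nodes beneath the spot center is
#' within `criterion_tol` of its steady-state temperature.  The bottom face
#' itself is a Dirichlet boundary, so "fully transmural" is judged on the
#' entire free column, the non-degenerate reading of a fully established
#' transmural profile.
#'
#' @param props a [thermal_properties()].
#' @param spot a [cold_spot()] (applied to the top face).
#' @param thickness slab thickness (cm), default 0.25.
#' @param lateral lateral extent (cm), default 3 (large against the
#'   thickness).
#' @param dx target grid spacing (cm); the transmural spacing is adjusted to
#'   divide the thickness exactly.
#' @param criterion_tol establishment tolerance (degC), default 1.0.
#' @param resolution reporting resolution (s), default 0.1.
#' @param max_time horizon (s); if the criterion is never met the return is
#'   `NA` with diagnostics in attributes.
#' @return establishment time (s), with attributes `steady_column` and
#'   `column_t` (the sampled column temperatures).
#' @export
transmural_establishment_time <- function(props, spot = cold_spot(c(1.5, 1.5)),
                                          thickness = 0.25, lateral = 3,
                                          dx = 0.03, criterion_tol = 1.0,
                                          resolution = 0.1, max_time = 120) {
  nz <- max(3L, round(thickness / dx) + 1L)
  dz <- thickness / (nz - 1)
  nl <- round(lateral / dx) + 1L
  fld <- temperature_field(c(nl, nl, nz), spacing = c(dx, dx, dz))
  stopifnot(spot$face == "top", nz >= 3)
  # steady state of the same configuration
  ss <- steady_state_heat(fld, props, list(spot))
  ic <- round(spot$center / dx) + 1L
  col_free <- 2:(nz - 1)
  ss_col <- ss$T[ic[1], ic[2], ]
  cur <- fld
  t <- 0
  samples <- list()
  while (t < max_time) {
    cur <- run_heat(cur, props, list(spot), resolution, t0 = t)
    t <- t + resolution
    colT <- cur$T[ic[1], ic[2], ]
    samples[[length(samples) + 1]] <- c(t, colT)
    if (max(abs(colT[col_free] - ss_col[col_free])) <= criterion_tol) {
      out <- t
      attr(out, "steady_column") <- ss_col
      attr(out, "column_t") <- do.call(rbind, samples)
      return(out)
    }
  }
  out <- NA_real_
  attr(out, "steady_column") <- ss_col
  attr(out, "column_t") <- do.call(rbind, samples)
  attr(out, "residual") <- max(abs(cur$T[ic[1], ic[2], col_free] -
                                     ss_col[col_free]))
  out
}

#' Relocate the active cold spot
#'
#' Deactivates the current spots at time `t` (their footprints revert to the
#' evolving field, rewarmed by the body-temperature faces) and activates a
#' new spot of the same geometry at `new_center`.
#'
#' @param spots list of [cold_spot()]s.
#' @param new_center new lateral center (cm).
#' @param t switch time (s).
#' @param domain optional lateral extents (cm) used to reject centers outside
#'   the domain.
#' @return the updated spot list.
#' @export
move_spot <- function(spots, new_center, t, domain = NULL) {
  if (inherits(spots, "cold_spot")) spots <- list(spots)
  if (!is.null(domain) &&
      (any(new_center < 0) || any(new_center > domain)))
    stop("new spot center lies outside the domain", call. = FALSE)
  act <- vapply(spots, function(s) t >= s$t_on && t < s$t_off, logical(1))
  tmpl <- if (any(act)) spots[[which(act)[1]]] else spots[[length(spots)]]
  for (k in which(act)) spots[[k]]$t_off <- t
  c(spots, list(cold_spot(new_center, tmpl$radius, tmpl$T_spot, tmpl$face,
                          t_on = t)))
}
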