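# Attract-anchor-drag control: schedule cold-spot placements and moves toward
# an inexcitable boundary, run the closed experiment, classify the outcome.

#' Drag-protocol description
#'
#' @param radius spot radius (cm), default 0.9.
#' @param T_spot spot temperature (degC), default 5.
#' @param move_step distance of each spot move (cm), default 1; 0 gives a
#'   static (anchor-only) experiment.
#' @param direction unit move direction; `NULL` picks the straight line to
#'   the nearest lateral boundary at run time.
#' @param dwell_rotations rotations of held anchoring required before a move
#'   (2D rule; also applied on top of the 3D transmural rule), default 2.
#' @param transmural_dwell 3D rule: move only after the cold column is
#'   transmurally established (default `TRUE`; ignored in 2D).
#' @param establish_tol transmural establishment tolerance (degC).
#' @param max_moves schedule cap.
#' @param anchor_margin residence slack (cm) added to the spot radius when
#'   judging anchoring: the phase singularity of a wave pinned to a cold
#'   disc orbits the disc *perimeter*, so tip samples land at and slightly
#'   beyond the nominal radius.  Default `max(0.1, 0.2 * radius)`.
#' @return object of class `drag_protocol`.
#' @export
drag_protocol <- function(radius = 0.9, T_spot = 5, move_step = 1,
                          direction = NULL, dwell_rotations = 2,
                          transmural_dwell = TRUE, establish_tol = 1.0,
                          max_moves = 12,
                          anchor_margin = max(0.1, 0.2 * radius)) {
  stopifnot(radius > 0, T_spot >= 0, T_spot <= 37, move_step >= 0,
            anchor_margin >= 0)
  structure(list(radius = radius, T_spot = T_spot, move_step = move_step,
                 direction = direction, dwell_rotations = dwell_rotations,
                 transmural_dwell = transmural_dwell,
                 establish_tol = establish_tol, max_moves = max_moves,
                 anchor_margin = anchor_margin),
            class = "drag_protocol")
}

#' Build the timed spot schedule for a drag experiment
#'
#' The first spot is centered on the current tip position (maximal overlap);
#' subsequent centers advance along the straight line to the target boundary
#' in `move_step` increments, the final position abutting the boundary.
#' Activation times are decided at run time by the dwell rule; here the
#' positions are laid out.
#'
#' @param tip current tip position `c(x, y)` (cm).
#' @param domain lateral domain extents (cm).
#' @param protocol a [drag_protocol()].
#' @return data.frame of spot centers `x`, `y` in visit order.
#' @export
build_drag_schedule <- function(tip, domain, protocol) {
  if (anyNA(tip)) stop("cannot build a drag schedule without a detected tip",
                       call. = FALSE)
  dir <- protocol$direction
  if (is.null(dir)) {
    # straight line to the nearest lateral boundary
    d_edges <- c(tip[1], domain[1] - tip[1], tip[2], domain[2] - tip[2])
    dir <- switch(which.min(d_edges),
                  c(-1, 0), c(1, 0), c(0, -1), c(0, 1))
  }
  dir <- dir / sqrt(sum(dir^2))
  centers <- list(tip)
  if (protocol$move_step > 0) {
    cur <- tip
    for (k in seq_len(protocol$max_moves)) {
      nxt <- cur + protocol$move_step * dir
      inside <- all(nxt >= 0) && all(nxt <= domain)
      centers[[length(centers) + 1]] <-
        pmin(pmax(nxt, c(0, 0)), domain)
      cur <- centers[[length(centers)]]
      if (!inside) break
    }
  }
  out <- do.call(rbind, lapply(centers, function(cc)
    data.frame(x = cc[1], y = cc[2])))
  out
}

# temperature map for a 2D step-profile spot (no heat PDE, per the 2D
# convention: cells inside the spot at T_spot, the rest at body temperature)
spot_temp_2d <- function(geometry, center, radius, T_spot, body_T = 37) {
  sh <- geometry$shape
  co <- lapply(1:2, function(a) (seq_len(sh[a]) - 1) * geometry$dx)
  dist <- outer(co[[1]] - center[1], co[[2]] - center[2],
                function(a, b) sqrt(a^2 + b^2))
  tmp <- array(body_T, sh)
  tmp[dist <= radius] <- T_spot
  tmp
}

# run one EP chunk and track the tip on the top layer; returns trajectory rows
chunk_track <- function(res, g, v_iso = -40) {
  if (g$ndim == 2) {
    track_tips(res$snapshots, res$times, g$shape[1], g$shape[2], g$dx, v_iso)
  } else {
    nz <- g$shape[3]
    lay <- region_nodes(g, zlim = c(nz, nz)) + 1L
    track_tips(res$snapshots[, lay, drop = FALSE], res$times,
               g$shape[1], g$shape[2], g$dx, v_iso)
  }
}

#' Estimate the spiral rotation period
#'
#' Measures the local activation cycle length: upstroke times (rising
#' crossings of -40 mV) are collected at probe nodes spread over the domain
#' and the median inter-activation interval is returned.  For a single
#' reentrant source the cycle length equals the rotation period, and the
#' estimate is robust to tip meander that defeats angle unwrapping.
#'
#' @param state a [tissue_state()] holding sustained reentry.
#' @param window tracking window (ms), default 700 (two to three cycles).
#' @return period (ms).
#' @export
estimate_period <- function(state, window = 700) {
  r <- run_tissue(state, window, snap_every = 2)
  g <- state$geometry
  probes <- unique(round(seq(1, g$N, length.out = 9)))
  cls <- unlist(lapply(probes, function(i) {
    v <- r$snapshots[, i]
    up <- which(v[-1] > -40 & v[-length(v)] <= -40)
    if (length(up) >= 2) diff(r$times[up + 1]) else numeric(0)
  }))
  if (!length(cls))
    stop("cannot estimate a rotation period: no repeated activations",
         call. = FALSE)
  stats::median(cls)
}

#' Run the attract-anchor-drag experiment
#'
#' Places a cold spot on the spiral tip, waits for anchoring, then walks the
#' spot toward the target boundary.  In 2D the spot imposes a step
#' temperature profile directly; in 3D the spot is a Dirichlet source on the
#' top face of the coupled bioheat field and, with the transmural dwell rule,
#' each move waits for the cold column to re-establish through the wall.
#' The run ends when the wave terminates, the schedule is exhausted, or
#' `max_time` is reached.
#'
#' @param state a [tissue_state()] containing sustained reentry.
#' @param protocol a [drag_protocol()].
#' @param props [thermal_properties()] (3D only).
#' @param chunk_ms controller decision interval (ms).
#' @param snap_every snapshot cadence (ms) for tip tracking.
#' @param max_time simulated-time cap (ms).
#' @param quiet_ms termination quiescence window (ms).
#' @param period_ms rotation period; `NULL` estimates it first.
#' @param heat_every_ms 3D heat-field update interval (ms of EP time).
#' @return run report: list with `outcome`, `trajectory`, `spots` (schedule
#'   with realized activation windows), `period_ms`, `anchor_latency_rot`
#'   (rotations from spot-on to anchoring), `t_end` (ms), `final_V`, and for
#'   3D runs `filaments` (last extracted set) and `temp_field`.
#' @export
run_drag_experiment <- function(state, protocol, props = thermal_properties(),
                                chunk_ms = 50, snap_every = 10,
                                max_time = 20000, quiet_ms = 500,
                                period_ms = NULL, heat_every_ms = 50) {
  g <- state$geometry
  nd <- g$ndim
  stopifnot(nd %in% c(2, 3))
  domain <- (g$shape[1:2] - 1L) * g$dx
  if (is.null(period_ms)) period_ms <- estimate_period(state)
  # locate the tip
  probe <- run_tissue(state, 2 * snap_every, snap_every = snap_every)
  state <- probe$state
  tr0 <- chunk_track(probe, g)
  tip <- c(utils::tail(tr0$x, 1), utils::tail(tr0$y, 1))
  if (anyNA(tip)) stop("no reentrant tip detected; cannot start the drag",
                       call. = FALSE)
  centers <- build_drag_schedule(tip, domain, protocol)
  # 3D thermal field co-located with the EP grid
  if (nd == 3) {
    fld <- temperature_field(g$shape, spacing = g$dx)
    steady_cache <- new.env(parent = emptyenv())
  }
  spots_log <- data.frame()
  traj <- data.frame()
  filament_log <- data.frame()
  pos <- 1L
  spot_on_t <- state$t
  anchored_since <- NA_real_
  anchor_angle <- 0        # unwrapped tip angle about the spot center (rad)
  last_ang <- NA_real_
  anchor_latency <- NA_real_
  obs_period <- NA_real_
  apply_spot <- function(state, center) {
    if (nd == 2) {
      set_temperature(state, spot_temp_2d(g, center, protocol$radius,
                                          protocol$T_spot))
    } else state  # 3D temperature comes from the heat field each chunk
  }
  cur_spot <- function(center, t_on, t_off = Inf)
    cold_spot(center, protocol$radius, protocol$T_spot, "top",
              t_on = t_on, t_off = t_off)
  state <- apply_spot(state, as.numeric(centers[1, ]))
  spots3d <- if (nd == 3) list(cur_spot(as.numeric(centers[1, ]),
                                        state$t / 1000))
  filaments <- NULL
  repeat {
    if (nd == 3) {
      # advance the heat field by the chunk, then impose it on the EP nodes
      fld <- run_heat(fld, props, spots3d, chunk_ms / 1000,
                      t0 = state$t / 1000)
      state <- set_temperature(state, as.numeric(fld$T))
    }
    res <- run_tissue(state, chunk_ms, snap_every = snap_every,
                      nernst_every = 5L)
    state <- res$state
    tr <- chunk_track(res, g)
    traj <- rbind(traj, tr)
    if (nd == 3) {
      ns <- nrow(res$snapshots)
      fil <- extract_filament(array(res$snapshots[ns - 1, ], g$shape),
                              array(res$snapshots[ns, ], g$shape), g$dx,
                              g$dx)
      filament_log <- rbind(filament_log, data.frame(
        t = res$times[ns], n = length(fil),
        length = if (length(fil)) attr(fil[[1]], "length") else NA_real_,
        transmural = if (length(fil)) attr(fil[[1]], "transmural") else FALSE,
        spot_pos = pos))
    }
    center <- as.numeric(centers[pos, ])
    # anchoring bookkeeping: continuous residence inside the spot radius
    # (plus the perimeter margin) while the unwrapped tip angle about the
    # spot center accumulates the required rotations
    tipin <- !is.na(tr$x) &
      sqrt((tr$x - center[1])^2 + (tr$y - center[2])^2) <=
        protocol$radius + protocol$anchor_margin
    if (nrow(tr) && all(tipin)) {
      if (is.na(anchored_since)) anchored_since <- tr$t[1]
      ang <- atan2(tr$y - center[2], tr$x - center[1])
      d <- diff(c(if (is.na(last_ang)) ang[1] else last_ang, ang))
      anchor_angle <- anchor_angle + sum((d + pi) %% (2 * pi) - pi)
      last_ang <- ang[length(ang)]
    } else {
      anchored_since <- NA_real_
      anchor_angle <- 0
      last_ang <- NA_real_
    }
    anchored <- abs(anchor_angle) >= 2 * pi * protocol$dwell_rotations
    if (anchored && is.na(anchor_latency)) {
      obs_period <- 2 * pi * (state$t - anchored_since) / abs(anchor_angle)
      anchor_latency <- (state$t - spot_on_t) / obs_period
    }
    # termination check
    tail_traj <- traj[traj$t > state$t - quiet_ms, ]
    finalV <- state$S[1, ]
    if (nrow(tail_traj) && all(tail_traj$n_tips == 0) &&
        all(finalV < -40) && (state$t - spot_on_t) > quiet_ms) {
      outcome <- "terminated"
      break
    }
    # dwell rule satisfied? then move (or finish the schedule)
    dwell_ok <- anchored
    if (nd == 3 && protocol$transmural_dwell) {
      key <- paste(round(center, 3), collapse = ",")
      ss <- steady_cache[[key]]
      if (is.null(ss)) {
        sfld <- temperature_field(g$shape, spacing = g$dx)
        ss <- steady_state_heat(sfld, props, list(cur_spot(center, 0)))
        steady_cache[[key]] <- ss
      }
      ic <- pmin(pmax(round(center / g$dx) + 1L, 1L), g$shape[1:2])
      nz <- g$shape[3]
      colT <- fld$T[ic[1], ic[2], 2:(nz - 1)]
      colS <- ss$T[ic[1], ic[2], 2:(nz - 1)]
      dwell_ok <- dwell_ok && max(abs(colT - colS)) <= protocol$establish_tol
    }
    final_interior <- all(centers[nrow(centers), ] > 0) &&
      all(centers[nrow(centers), ] < domain)
    if (dwell_ok && pos == nrow(centers) && pos > 1L && final_interior) {
      # schedule exhausted with anchoring held at an interior position:
      # the drag is complete (termination is only expected at a boundary)
      outcome <- "dragged"
      break
    }
    if (dwell_ok && pos < nrow(centers)) {
      spots_log <- rbind(spots_log,
                         data.frame(x = center[1], y = center[2],
                                    radius = protocol$radius,
                                    t_on = spot_on_t, t_off = state$t))
      pos <- pos + 1L
      spot_on_t <- state$t
      anchored_since <- NA_real_
      anchor_angle <- 0
      last_ang <- NA_real_
      center <- as.numeric(centers[pos, ])
      state <- apply_spot(state, center)
      if (nd == 3)
        spots3d <- move_spot(spots3d, center, state$t / 1000, domain)
    }
    if (state$t >= max_time) {
      outcome <- if (anchored && pos > 1) "dragged"
                 else if (anchored) "anchored"
                 else "unaffected"
      break
    }
  }
  spots_log <- rbind(spots_log,
                     data.frame(x = centers[pos, 1], y = centers[pos, 2],
                                radius = protocol$radius, t_on = spot_on_t,
                                t_off = state$t))
  # final classification via the generic classifier
  period_cls <- if (!is.na(obs_period)) obs_period else period_ms
  outcome2 <- classify_outcome(traj, spots_log, state$S[1, ], period_cls,
                               k_rot = protocol$dwell_rotations,
                               quiet_ms = quiet_ms,
                               margin = protocol$anchor_margin)
  if (exists("outcome") && outcome == "terminated") outcome2 <- "terminated"
  if (nd == 3) {
    # extract the filament from a final snapshot pair
    r2 <- run_tissue(state, 2 * snap_every, snap_every = snap_every)
    state <- r2$state
    A1 <- array(r2$snapshots[1, ], g$shape)
    A2 <- array(r2$snapshots[2, ], g$shape)
    filaments <- extract_filament(A1, A2, g$dx, g$dx)
  }
  list(outcome = outcome2, trajectory = traj, spots = spots_log,
       period_ms = period_ms, anchored_period_ms = obs_period,
       anchor_latency_rot = anchor_latency,
       t_end = state$t, final_V = state$S[1, ],
       filaments = if (nd == 3) filaments,
       filament_log = if (nd == 3) filament_log,
       temp_field = if (nd == 3) fld,
       state = state)
}
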