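# Metrology: action-potential metrics, current ratios, phase-singularity
# (spiral tip) detection, rotation counting, outcome classification and
# scroll-filament extraction.

#' Action-potential metrics from a voltage trace
#'
#' Measures resting membrane potential, peak voltage, amplitude and the
#' action-potential durations APD40/50/90 on the final action potential of a
#' `(t, V)` trace.  The upstroke is located at the maximal dV/dt after the
#' last stimulus onset; RMP is the mean pre-stimulus voltage; APD_X runs from
#' the upstroke until the *first* crossing below `peak - X% * amplitude`
#' (linear interpolation between samples).  First-crossing semantics matter:
#' with the cold spike-dome morphology the 40% level is crossed on the early
#' spike, which is what makes APD40 collapse at low temperature while APD90
#' grows.
#'
#' @param trace data.frame with columns `t` (ms) and `V` (mV), optionally
#'   `Ca_i` (mM) for the Ca-transient metrics.
#' @param stim_times stimulus onsets (ms); the last one that is followed by
#'   data delimits the measured AP.
#' @param levels repolarization percentages to measure (default 40, 50, 90).
#' @return object of class `ap_metrics`: list with `captured` (logical),
#'   `RMP`, `peak`, `amplitude` (mV), `apd` (named vector, ms),
#'   `cat_peak`/`cat_width` (Ca-transient peak, mM, and width at half
#'   prominence, ms; `NA` without a `Ca_i` column), and `upstroke_t` (ms).
#'   If no AP is elicited, `captured` is `FALSE` and the APDs are `NA` (an
#'   explicit no-capture result, not an error).
#' @export
ap_metrics <- function(trace, stim_times = 0, levels = c(40, 50, 90)) {
  stopifnot(is.data.frame(trace), all(c("t", "V") %in% names(trace)),
            nrow(trace) > 3)
  s0 <- max(stim_times[stim_times <= max(trace$t)])
  pre <- trace[trace$t < s0, , drop = FALSE]
  rmp <- if (nrow(pre)) mean(pre$V) else trace$V[1]
  post <- trace[trace$t >= s0, , drop = FALSE]
  dv <- diff(post$V) / diff(post$t)
  iup <- which.max(dv)
  t_up <- post$t[iup]
  ipk <- which.max(post$V)
  peak <- post$V[ipk]
  amp <- peak - rmp
  captured <- amp > 40 && peak > -20
  apd <- setNames(rep(NA_real_, length(levels)),
                  paste0("APD", levels))
  if (captured) {
    seg <- post[ipk:nrow(post), , drop = FALSE]
    for (k in seq_along(levels)) {
      lvl <- peak - levels[k] / 100 * amp
      j <- which(seg$V < lvl)[1]
      if (!is.na(j) && j > 1) {
        v0 <- seg$V[j - 1]; v1 <- seg$V[j]
        tc <- seg$t[j - 1] + (lvl - v0) / (v1 - v0) *
          (seg$t[j] - seg$t[j - 1])
        apd[k] <- tc - t_up
      }
    }
  }
  cat_peak <- cat_width <- NA_real_
  if ("Ca_i" %in% names(trace) && captured) {
    ca <- post$Ca_i
    cat_peak <- max(ca)
    base <- ca[1]
    half <- base + (cat_peak - base) / 2
    above <- which(ca >= half)
    if (length(above) > 1)
      cat_width <- post$t[max(above)] - post$t[min(above)]
  }
  structure(list(captured = captured, RMP = rmp, peak = peak,
                 amplitude = amp, apd = apd, cat_peak = cat_peak,
                 cat_width = cat_width, upstroke_t = t_up),
            class = "ap_metrics")
}

#' @export
print.ap_metrics <- function(x, ...) {
  if (!x$captured) {
    cat("<ap_metrics> no capture\n")
    return(invisible(x))
  }
  cat(sprintf("<ap_metrics> RMP %.1f mV, peak %.1f mV, amplitude %.1f mV\n",
              x$RMP, x$peak, x$amplitude))
  cat("  ", paste(names(x$apd), sprintf("%.1f ms", x$apd), sep = " = ",
                  collapse = ", "), "\n")
  invisible(x)
}

#' Relative change of a peak current with temperature
#'
#' `I_ratio = (Ipeak(T) - Ipeak(37)) / Ipeak(37)`, sign preserving, so a
#' current that shrinks at cold has a negative ratio regardless of its
#' direction of flow.
#'
#' @param ipeak_t peak current at temperature T (pA/pF).
#' @param ipeak_37 peak current at 37 degC (pA/pF), non-zero.
#' @return the dimensionless ratio.
#' @export
current_ratio <- function(ipeak_t, ipeak_37) {
  if (any(ipeak_37 == 0))
    stop("undefined ratio: zero baseline peak current", call. = FALSE)
  (ipeak_t - ipeak_37) / ipeak_37
}

# ---- phase-singularity detection ------------------------------------------

#' Detect spiral-wave tips (phase singularities) in a voltage-snapshot pair
#'
#' Builds a phase field from two voltage snapshots a short interval apart,
#' `phi = atan2(V(t) - V_iso, V(t - dt) - V_iso)`, and locates the
#' plaquettes around which the phase winds by +-2*pi.  Tip coordinates are
#' plaquette centers (sub-grid via the grid spacing); the winding sign is the
#' topological charge.
#'
#' @param V1,V2 numeric matrices (nx x ny): consecutive snapshots, `V1`
#'   earlier.
#' @param dx grid spacing (cm).
#' @param v_iso isoline voltage (mV), default -40 (mid amplitude).
#' @return data.frame with columns `x`, `y` (cm) and `charge` (+1/-1); zero
#'   rows when there is no reentrant activity.
#' @export
detect_tips <- function(V1, V2, dx = 0.03, v_iso = -40) {
  stopifnot(is.matrix(V1), all(dim(V1) == dim(V2)))
  ph <- atan2(V2 - v_iso, V1 - v_iso)
  nx <- nrow(ph); ny <- ncol(ph)
  wrap <- function(a) (a + pi) %% (2 * pi) - pi
  # phase differences along edges
  dphx <- wrap(ph[-1, , drop = FALSE] - ph[-nx, , drop = FALSE]) # (nx-1) x ny
  dphy <- wrap(ph[, -1, drop = FALSE] - ph[, -ny, drop = FALSE]) # nx x (ny-1)
  # winding around each plaquette (i,j)-(i+1,j)-(i+1,j+1)-(i,j+1)
  w <- dphx[, -ny, drop = FALSE] + dphy[-1, , drop = FALSE] -
       dphx[, -1, drop = FALSE] - dphy[-nx, , drop = FALSE]
  idx <- which(abs(w) > pi, arr.ind = TRUE)
  if (!nrow(idx))
    return(data.frame(x = numeric(0), y = numeric(0), charge = numeric(0)))
  data.frame(x = (idx[, 1] - 0.5) * dx, y = (idx[, 2] - 0.5) * dx,
             charge = sign(w[idx]))
}

#' Track spiral tips through a snapshot stack
#'
#' Applies [detect_tips()] to consecutive snapshot pairs and links the
#' strongest match through time by nearest-neighbor continuation.
#'
#' @param snaps matrix (n_snapshots x n_nodes) of voltage snapshots.
#' @param times snapshot times (ms).
#' @param nx,ny grid dimensions.
#' @param dx grid spacing (cm).
#' @param v_iso isoline voltage (mV).
#' @return data.frame of class `tip_trajectory`: `t` (ms), `x`, `y` (cm),
#'   `charge`, `n_tips` (tips present in that frame).  Frames without tips
#'   contribute `NA` positions so that tip loss is visible.
#' @export
track_tips <- function(snaps, times, nx, ny, dx = 0.03, v_iso = -40) {
  n <- nrow(snaps)
  stopifnot(n >= 2, length(times) == n)
  out <- vector("list", n - 1)
  prev <- NULL
  for (k in 2:n) {
    V1 <- matrix(snaps[k - 1, ], nx, ny)
    V2 <- matrix(snaps[k, ], nx, ny)
    tips <- detect_tips(V1, V2, dx, v_iso)
    if (nrow(tips)) {
      if (!is.null(prev)) {
        d2 <- (tips$x - prev$x)^2 + (tips$y - prev$y)^2
        pick <- which.min(d2)
      } else pick <- 1L
      prev <- tips[pick, , drop = FALSE]
      out[[k - 1]] <- data.frame(t = times[k], x = prev$x, y = prev$y,
                                 charge = prev$charge, n_tips = nrow(tips))
    } else {
      out[[k - 1]] <- data.frame(t = times[k], x = NA_real_, y = NA_real_,
                                 charge = NA_real_, n_tips = 0L)
    }
  }
  structure(do.call(rbind, out), class = c("tip_trajectory", "data.frame"))
}

#' Count spiral rotations along a tip trajectory
#'
#' Cumulative unwrapped angle of the tip about a center, divided by 2*pi.
#' By default the center is the running centroid of the trajectory; once a
#' spiral is anchored, counting about the anchoring spot center (passed via
#' `center`) is the more meaningful convention.
#'
#' @param traj a data.frame with `t`, `x`, `y` (NA rows = tip lost).
#' @param center optional fixed center `c(x, y)` (cm); `NULL` = running
#'   centroid.
#' @param window optional time window `c(t0, t1)` (ms).
#' @return list with `rotations` (absolute cumulative turns, fractional),
#'   `lost` (`TRUE` if the tip disappeared inside the window; rotations are
#'   then counted up to the loss).
#' @export
count_rotations <- function(traj, center = NULL, window = NULL) {
  tr <- as.data.frame(traj)
  if (!is.null(window)) tr <- tr[tr$t >= window[1] & tr$t <= window[2], ]
  lost <- anyNA(tr$x)
  if (lost) {
    first_na <- which(is.na(tr$x))[1]
    tr <- tr[seq_len(first_na - 1), , drop = FALSE]
  }
  if (nrow(tr) < 3) return(list(rotations = 0, lost = lost))
  if (is.null(center)) {
    cx <- cumsum(tr$x) / seq_len(nrow(tr))
    cy <- cumsum(tr$y) / seq_len(nrow(tr))
  } else {
    cx <- rep(center[1], nrow(tr)); cy <- rep(center[2], nrow(tr))
  }
  ang <- atan2(tr$y - cy, tr$x - cx)
  d <- diff(ang)
  d <- (d + pi) %% (2 * pi) - pi
  list(rotations = abs(sum(d)) / (2 * pi), lost = lost)
}

#' Classify the outcome of a cold-spot control run
#'
#' Ordinal outcome of an attract-anchor-drag experiment from the tip
#' trajectory, the spot schedule and the final voltage state:
#' `anchored` - tip stayed within the spot radius for at least
#' `k_rot` consecutive rotations at some spot position; `dragged` - anchored
#' at two or more successive spot positions; `terminated` - no tips and no
#' excited nodes (V > -40 mV) over the final `quiet_ms`; `detached` -
#' anchoring established then lost without termination; `unaffected` - none
#' of the above.
#'
#' @param traj tip trajectory ([track_tips()]).
#' @param spots data.frame of the spot schedule: `x`, `y`, `radius`, `t_on`,
#'   `t_off` (ms).
#' @param final_V numeric vector/matrix: last voltage snapshot (mV).
#' @param period_ms estimated rotation period (ms) used to convert residence
#'   time to rotations.
#' @param k_rot rotations of residence required for anchoring (default 2).
#' @param quiet_ms quiescence window for termination (default 500 ms).
#' @param margin residence slack (cm) added to the spot radius (an anchored
#'   tip orbits the spot perimeter); 0 is the strict reading.
#' @return character scalar: one of `"anchored"`, `"dragged"`, `"detached"`,
#'   `"terminated"`, `"unaffected"`.
#' @export
classify_outcome <- function(traj, spots, final_V, period_ms,
                             k_rot = 2, quiet_ms = 500, margin = 0) {
  tr <- as.data.frame(traj)
  terminated <- FALSE
  tail_tr <- tr[tr$t > max(tr$t) - quiet_ms, ]
  if (nrow(tail_tr) && all(tail_tr$n_tips == 0) &&
      all(final_V < -40, na.rm = TRUE))
    terminated <- TRUE
  n_anch <- 0L
  if (!is.null(spots) && nrow(spots)) {
    for (k in seq_len(nrow(spots))) {
      sp <- spots[k, ]
      w <- tr[tr$t >= sp$t_on & tr$t <= min(sp$t_off, max(tr$t)), ]
      w <- w[!is.na(w$x), ]
      if (!nrow(w)) next
      inside <- sqrt((w$x - sp$x)^2 + (w$y - sp$y)^2) <= sp$radius + margin
      # longest run of consecutive residence, in rotations
      r <- rle(inside)
      best <- if (any(r$values)) max(r$lengths[r$values]) else 0
      dt_frame <- median(diff(w$t))
      if (best * dt_frame >= k_rot * period_ms) n_anch <- n_anch + 1L
    }
  }
  if (n_anch >= 2) {
    if (terminated) "terminated" else "dragged"
  } else if (terminated) {
    "terminated"
  } else if (n_anch == 1) {
    # anchored once: did it stay anchored to the end of that spot's window?
    "anchored"
  } else "unaffected"
}

#' Extract scroll-wave filaments from a 3D snapshot pair
#'
#' Runs per-layer tip detection on two consecutive voltage volumes and links
#' the detected tips across layers by nearest-neighbor chaining into
#' filament polylines.
#'
#' @param A1,A2 3D arrays (nx x ny x nz): consecutive voltage volumes.
#' @param dx lateral grid spacing (cm).
#' @param dz layer spacing (cm).
#' @param v_iso isoline voltage (mV).
#' @param link_max maximal lateral jump between layers (cm) for chaining,
#'   default 3 grid cells.
#' @return list of filaments; each a data.frame `x`, `y`, `z`, `charge` with
#'   attributes `length` (polyline arc length, cm) and `transmural`
#'   (touches both the first and last layer).  Empty list without reentry.
#' @export
extract_filament <- function(A1, A2, dx = 0.03, dz = dx, v_iso = -40,
                             link_max = 3 * dx) {
  stopifnot(length(dim(A1)) == 3, all(dim(A1) == dim(A2)))
  nz <- dim(A1)[3]
  per_layer <- lapply(seq_len(nz), function(k) {
    tips <- detect_tips(A1[, , k], A2[, , k], dx, v_iso)
    if (nrow(tips)) tips$z <- (k - 1) * dz
    tips
  })
  used <- lapply(per_layer, function(d) rep(FALSE, nrow(d)))
  filaments <- list()
  for (k0 in seq_len(nz)) {
    d0 <- per_layer[[k0]]
    if (!nrow(d0)) next
    for (s in seq_len(nrow(d0))) {
      if (used[[k0]][s]) next
      chain <- d0[s, , drop = FALSE]
      used[[k0]][s] <- TRUE
      cur <- d0[s, ]
      if (k0 < nz) for (k in (k0 + 1):nz) {
        dk <- per_layer[[k]]
        if (!nrow(dk)) break
        free <- which(!used[[k]])
        if (!length(free)) break
        dd <- sqrt((dk$x[free] - cur$x)^2 + (dk$y[free] - cur$y)^2)
        j <- free[which.min(dd)]
        if (min(dd) > link_max) break
        chain <- rbind(chain, dk[j, , drop = FALSE])
        used[[k]][j] <- TRUE
        cur <- dk[j, ]
      }
      len <- if (nrow(chain) > 1)
        sum(sqrt(diff(chain$x)^2 + diff(chain$y)^2 + diff(chain$z)^2)) else 0
      attr(chain, "length") <- len
      attr(chain, "transmural") <-
        (min(chain$z) <= 0 + 1e-9) && (max(chain$z) >= (nz - 1) * dz - 1e-9)
      filaments[[length(filaments) + 1]] <- chain
    }
  }
  filaments
}
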