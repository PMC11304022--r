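#' Maximal-conductance parameter set for the atrial ionic model
#'
#' Builds the parameter set of the temperature-sensitive
#' Courtemanche-Ramirez-Nattel (CRN) human atrial cardiomyocyte model used
#' throughout the package.  The healthy working-myocardium variant carries the
#' baseline 37 degC conductances (nS/pF): `g_K1 = 0.117`, `g_to = 0.1652`,
#' `g_Kr = 0.0294`, `g_CaL = 0.1238`; all remaining parameters are the CRN
#' defaults.  The `"cAF"` variant is the chronic-atrial-fibrillation
#' electrical-remodeling set, obtained from the healthy set with
#' [apply_caf_remodeling()].
#'
#' @param variant `"healthy"` or `"cAF"`.
#' @param ik1_remodeling how "peak IK1 increased by 250%" is interpreted when
#'   building the cAF variant: `"scale"` (conductance set to 250% of baseline,
#'   i.e. x2.5, the convention of the cAF remodeling literature) or `"add"`
#'   (+250%, i.e. x3.5).
#' @return An object of class `crn_params`: a list with elements
#'   `conductances` (named numeric, nS/pF and pump/exchanger maxima),
#'   `kinetic_shifts` (named steady-state voltage displacements, mV),
#'   `tau_scales` (named time-constant multipliers), `cm` (membrane
#'   capacitance, pF) and `variant`.
#' @export
model_parameters <- function(variant = c("healthy", "cAF"),
                             ik1_remodeling = c("scale", "add")) {
  variant <- match.arg(variant)
  ik1_remodeling <- match.arg(ik1_remodeling)
  p <- structure(list(
    conductances = c(
      g_Na = 7.8, g_K1 = 0.117, g_to = 0.1652, g_Kur = NA_real_,
      g_Kr = 0.0294, g_Ks = 0.12941176, g_CaL = 0.1238,
      g_bNa = 0.0006744375, g_bCa = 0.001131,
      i_NaK_max = 0.59933874, i_pCa_max = 0.275, i_NaCa_max = 1600,
      k_rel = 30, i_up_max = 0.005
    ),
    # g_Kur is voltage dependent in CRN (0.005 + 0.05/(1+exp(-(V-15)/13)));
    # kept as NA in the flat vector and handled inside the kernels.
    kinetic_shifts = c(h = 0, oa = 0, d = 0),
    tau_scales = c(d = 1),
    cm = 100,
    variant = "healthy"
  ), class = "crn_params")
  validate_params(p)
  if (variant == "cAF") p <- apply_caf_remodeling(p, ik1_remodeling)
  p
}

validate_params <- function(p) {
  stopifnot(inherits(p, "crn_params"))
  g <- p$conductances[setdiff(names(p$conductances), "g_Kur")]
  if (any(!is.finite(g)) || any(g < 0))
    stop("conductances must be finite and >= 0", call. = FALSE)
  if (any(p$tau_scales <= 0))
    stop("tau_scales must be > 0", call. = FALSE)
  invisible(p)
}

#' @export
print.crn_params <- function(x, ...) {
  cat("<crn_params> variant:", x$variant, "\n")
  cat("  conductances (nS/pF):\n")
  print(round(x$conductances, 6))
  if (any(x$kinetic_shifts != 0))
    cat("  steady-state shifts (mV):",
        paste(names(x$kinetic_shifts), x$kinetic_shifts, sep = "=",
              collapse = " "), "\n")
  if (any(x$tau_scales != 1))
    cat("  tau scales:", paste(names(x$tau_scales), x$tau_scales, sep = "=",
                               collapse = " "), "\n")
  invisible(x)
}

#' Chronic-AF electrical remodeling of the healthy parameter set
#'
#' Applies the chronic atrial fibrillation (cAF) remodeling to a healthy
#' parameter set: transient-outward conductance down-regulated by 85%
#' (`g_to` x 0.15), L-type Ca2+ conductance down-regulated by 74%
#' (`g_CaL` x 0.26), inward-rectifier conductance raised to 250% of baseline
#' (`g_K1` x 2.5 with `ik1_remodeling = "scale"`, x 3.5 with `"add"`), the
#' ICaL activation time constant increased by 62% (tau_d x 1.62), the fast
#' Na+ inactivation steady-state curve shifted by +1.6 mV, and the activation
#' curves of Ito and ICaL shifted by +16 mV and -5.4 mV respectively.
#'
#' @param params a healthy `crn_params` object.
#' @param ik1_remodeling `"scale"` (x2.5, default) or `"add"` (x3.5).
#' @return the remodeled `crn_params` with `variant = "cAF"`.  Applying the
#'   remodeling to an already-remodeled set is an error.
#' @export
apply_caf_remodeling <- function(params, ik1_remodeling = c("scale", "add")) {
  validate_params(params)
  ik1_remodeling <- match.arg(ik1_remodeling)
  if (params$variant != "healthy")
    stop("cAF remodeling can only be applied to the healthy variant ",
         "(already remodeled?)", call. = FALSE)
  p <- params
  p$conductances[["g_to"]] <- p$conductances[["g_to"]] * 0.15
  p$conductances[["g_CaL"]] <- p$conductances[["g_CaL"]] * 0.26
  p$conductances[["g_K1"]] <- p$conductances[["g_K1"]] *
    if (ik1_remodeling == "scale") 2.5 else 3.5
  p$tau_scales[["d"]] <- 1.62
  p$kinetic_shifts[["h"]] <- 1.6
  p$kinetic_shifts[["oa"]] <- 16
  p$kinetic_shifts[["d"]] <- -5.4
  p$variant <- "cAF"
  validate_params(p)
  p
}

#' Q10 temperature-scaling factor set
#'
#' The per-current Q10 factors used to scale gating kinetics with temperature:
#' INa 3.0, Ito 2.2, IKur 2.2, IKr 3.3, IKs 2.57, ICaL 2.2.  Currents without
#' voltage gates (IK1), pumps, exchangers, background currents and the
#' intracellular Ca2+ handling fluxes are not listed and are left
#' temperature-independent; `scaled_currents` allows restricting the scaled
#' subset further for sensitivity studies.
#'
#' @param scaled_currents character vector naming the currents whose gates are
#'   scaled (default: all six listed).
#' @param fca_scaled should the Ca-dependent inactivation gate of ICaL
#'   (`f_Ca`, time constant 2 ms) be scaled along with the voltage gates `d`
#'   and `f`?  `f_Ca` is a Ca2+-sensing process rather than a voltage-gated
#'   transition, so it is left temperature-independent by default, like the
#'   rest of the intracellular Ca2+ handling.
#' @return an object of class `q10_set` (named numeric vector with
#'   `scaled_currents` and `fca_scaled` attributes).
#' @export
q10_set <- function(scaled_currents = c("INa", "Ito", "IKur", "IKr", "IKs",
                                        "ICaL"),
                    fca_scaled = FALSE) {
  q <- c(INa = 3.0, Ito = 2.2, IKur = 2.2, IKr = 3.3, IKs = 2.57, ICaL = 2.2)
  stopifnot(all(scaled_currents %in% names(q)), is.logical(fca_scaled))
  if (any(q <= 1)) stop("all Q10 factors must exceed 1")
  structure(q, scaled_currents = scaled_currents, fca_scaled = fca_scaled,
            class = "q10_set")
}

#' Temperature scaling factor Q(T)
#'
#' Arrhenius-type fold change of a gating rate at temperature `T` relative to
#' body temperature: `Q(T) = Q10^((T - 37)/10)`.
#'
#' @param q10 Q10 factor (> 0).
#' @param T temperature in degC, within \[0, 45\].
#' @return the dimensionless rate multiplier; 1 at 37 degC, strictly
#'   increasing in `T` for `q10 > 1`.
#' @export
q_factor <- function(q10, T) {
  if (any(q10 <= 0)) stop("q10 must be positive", call. = FALSE)
  if (any(T < 0 | T > 45)) stop("T must lie in [0, 45] degC", call. = FALSE)
  q10^((T - 37) / 10)
}

#' Per-current gating-rate scalers at a given temperature
#'
#' Evaluates `Q(T)` for each current of the Q10 set.  Both rate constants of
#' every gate of a listed current are multiplied by this factor (equivalently
#' the time constant is divided by it), so steady-state activation/
#' inactivation curves are temperature invariant.  Currents excluded from
#' `scaled_currents` get a scaler of exactly 1.
#'
#' @param params a `crn_params` object (kept in the signature so variants can
#'   override scaling behavior; the scalers themselves do not depend on the
#'   conductances).
#' @param q10s a `q10_set`.
#' @param T temperature in degC.
#' @return named numeric vector of rate multipliers, one per current in the
#'   order `INa, Ito, IKur, IKr, IKs, ICaL`.
#' @export
scale_kinetics <- function(params, q10s = q10_set(), T = 37) {
  validate_params(params)
  stopifnot(inherits(q10s, "q10_set"))
  on <- names(q10s) %in% attr(q10s, "scaled_currents")
  s <- ifelse(on, q_factor(as.numeric(q10s), T), 1)
  names(s) <- names(q10s)
  s
}

# flat named vector consumed by the C++ kernels
kernel_params <- function(params) {
  g <- params$conductances
  g[["g_Kur"]] <- 0  # placeholder; voltage-dependent form lives in the kernel
  g
}

# 7-element rate-scaler vector for the kernels: six per-current multipliers
# plus the fCa slot (tied to ICaL only when fca_scaled is set)
kernel_scalers <- function(params, q10s, T) {
  s <- scale_kinetics(params, q10s, T)
  c(s, fCa = if (isTRUE(attr(q10s, "fca_scaled"))) unname(s[["ICaL"]]) else 1)
}
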