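---
title: "Methods: temperature-sensitive atrial electrophysiology and cold-spot wave control"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: temperature-sensitive atrial electrophysiology and cold-spot wave control}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(cryodrag)
```

# The model

`cryodrag` simulates thermal control of reentrant excitation waves in human
atrial tissue.  Three coupled components make up the framework.

**Membrane kinetics.** Each node carries the Courtemanche–Ramirez–Nattel
(CRN) human atrial ionic model: 12 membrane currents
(INa, IK1, Ito, IKur, IKr, IKs, the Na+ and Ca2+ background currents, the
Na+/K+ pump, the sarcolemmal Ca2+ pump, the Na+/Ca2+ exchanger and ICaL),
15 gating variables and 5 intracellular concentrations, with

$$\frac{dV}{dt} = -\frac{I_\mathrm{ion} + I_\mathrm{stim}}{C_m}.$$

Currents are expressed in pA/pF, which makes the voltage equation
dimensionally self-contained; the cell capacitance $C_m = 100$ pF enters the
concentration balances.  The working-myocardium baseline overrides four CRN
maximal conductances ($g_{K1} = 0.117$, $g_{to} = 0.1652$,
$g_{Kr} = 0.0294$, $g_{CaL} = 0.1238$ nS/pF); all remaining parameters are
CRN defaults.  The chronic-AF variant applies the standard electrical
remodeling: $g_{to} \times 0.15$, $g_{CaL} \times 0.26$,
$g_{K1} \times 2.5$ (250% of baseline; the additive reading, $\times 3.5$,
is selectable), $\tau_d \times 1.62$, and steady-state shifts of +1.6 mV
(fast Na+ inactivation), +16 mV (Ito activation) and −5.4 mV (ICaL
activation).  The multiplicative IK1 reading is the convention of the cAF
remodeling literature and yields the short, triangular cAF action potential
that sustains stable reentry, which is the property the variant exists for.

**Temperature.** Temperature acts on the membrane in two ways.

1. *Gating kinetics* scale by the Arrhenius factor
   $Q(T) = Q_{10}^{(T-37)/10}$, applied to both rate constants of each gate
   (equivalently, the time constant is divided by $Q(T)$), so the
   steady-state activation/inactivation curves are temperature invariant.
   The per-current $Q_{10}$ set is INa 3.0, Ito 2.2, IKur 2.2, IKr 3.3,
   IKs 2.57, ICaL 2.2.  Currents with no published factor — IK1 (which has
   no gates), pumps, exchangers, background currents and the SR Ca2+
   handling — are left temperature independent; `q10_set()` exposes the
   scaled subset for sensitivity studies.  The Ca2+-sensing inactivation
   gate of ICaL (`f_Ca`, time constant 2 ms) is treated as part of Ca2+
   handling and left unscaled by default (`fca_scaled = FALSE`); flipping
   the switch changes the cold AP by well under 1%, so nothing downstream
   hinges on this choice.
2. *Thermodynamics*: the absolute temperature enters every Nernst potential
   and the Boltzmann voltage factors of the Na+/K+ pump and Na+/Ca2+
   exchanger through $RT/F$.  This is what elevates the resting membrane
   potential in the cold: cooling from 37 °C to 5 °C raises $E_K$ by about
   +9 mV, and the equilibrated resting potential follows it almost exactly
   — the measured shift (`equilibrate()` at both temperatures) is +9.9 mV,
   linear in $T$ between those extremes.

**Tissue.** Space is a regular grid (default $dx = 0.03$ cm) with diffusive
coupling $D\,\nabla^2 V$, scalar $D = 0.0025$ cm²/ms, centered second-order
differences, and zero-flux boundaries implemented by the conservative
half-point mirror (the domain integral of the discrete Laplacian vanishes
identically).  The temperature field obeys heat conduction
$(\rho C)\,\partial T/\partial t = \nabla\cdot(k_t \nabla T)$ with
$\rho = 1050$ kg/m³, $C = 4219$ J/(kg K), $k_t = 0.7$ W/(m K) (diffusivity
$\kappa \approx 1.58\times10^{-3}$ cm²/s), no perfusion source, zero-flux
vertical faces, and Dirichlet body temperature (37 °C) on the horizontal
faces except where a cold spot imposes its own temperature on the face
layer; depth penetration of the cold is purely conductive.

# Numerics

* **Time stepping.** Voltage and concentrations advance by forward Euler at
  $dt \le 0.02$ ms; gates use the Rush–Larsen exponential update
  $x \leftarrow x_\infty + (x - x_\infty)e^{-dt/\tau}$, the standard
  explicit scheme for gates whose time constants approach the step
  ($\tau_m$ falls below 0.01 ms at rest, where plain Euler on the gate
  would be unstable).  Step-halving changes APD90 by ≈0.2% and conduction
  velocity by ≈1%, within the convergence bands asserted by the tests.
* **Rate tabulation.** All voltage-dependent quantities (gate
  $x_\infty, \tau$; rectification factors; pump/exchanger Boltzmann terms;
  the per-gate exponential factors) are tabulated on a 0.05-mV grid over
  [−120, 80] mV and linearly interpolated, the standard cardiac-solver
  optimization.  A test compares the tabulated kernel against direct
  evaluation of the published formulas.
* **Per-temperature caching.** Tissue nodes are grouped by temperature
  quantized to 0.1 °C; each group owns its thermodynamic and exponential
  tables, cached for the session, so coupled runs that refresh the
  temperature field every few milliseconds pay tabulation once per level.
* **Nernst refresh.** Intracellular concentrations drift slowly, so tissue
  runs may refresh the per-node Nernst potentials every few steps
  (`nernst_every`); the default of 1 (every step) is exact, and the
  experiment drivers use 5 (0.1 ms), which perturbs V by under $10^{-4}$ mV.
* **Heat solver.** Explicit diffusion at 90% of the stability bound
  $dt \le (2\kappa\sum_a h_a^{-2})^{-1}$ (about 0.1 s in 3D at 0.03 cm),
  with Dirichlet values re-imposed after every step — this preserves the
  discrete maximum principle, which the tests assert stepwise.  The
  transmural axis uses $dz = \mathrm{thickness}/(n_z-1)$ so that walls that
  are not integer multiples of 0.03 cm (such as 0.25 cm) are represented
  exactly; lateral spacing stays at the EP resolution.
* **Gate clamping.** After each update gates are clamped to [0, 1] and the
  clamp count is reported; in healthy runs it stays at zero, and a growing
  count flags instability before voltage blow-up (which aborts with time
  and location at |V| > 200 mV).

# Protocols and measurement conventions

* **Stimulus.** Rectangular 2-ms pulses of negative (depolarizing) current;
  the default amplitude is twice the diastolic threshold found by bisection
  at the run's temperature.  Cable stimuli cover a 0.45-cm end segment so
  that capture survives the diffusive sink at higher $D$.
* **Equilibration.** 60 s of unstimulated integration at fixed temperature,
  with the residual drift checked against 10⁻³ mV/s and results cached per
  (parameter set, temperature).
* **AP metrology.** RMP is the pre-stimulus mean; the upstroke is the
  maximal dV/dt; APD$_X$ runs from the upstroke to the *first* crossing of
  $V_\mathrm{peak} - X\% \cdot \mathrm{amplitude}$ (percent of amplitude,
  the field convention), linearly interpolated.  First-crossing semantics
  are load-bearing in the cold: below ≈20 °C the AP becomes spike-dome, the
  40% level is crossed on the early spike, and APD40 collapses roughly
  ninefold while APD90 grows ninefold.  The 50% level at 5 °C is grazed by
  the post-spike dip (the dip bottoms ≈1.5 mV below the level), so APD50
  also reads on the spike and the sixfold change appears as a sixfold
  *decrease* here; the magnitude matches the sixfold figure reported for
  this quantity, but its direction depends on morphology details within
  ≈2 mV, which is worth knowing before comparing conventions.
* **Conduction velocity.** 6-cm cable, activation times (max dV/dt) at
  sensors ≥1.5 cm apart and ≥1 cm from the ends.  At 37 °C with the printed
  $D$ this measures 73.7 cm/s on the 0.03-cm grid (the calibration target
  for this configuration is 69.75 cm/s; the ≈6% excess is consistent with
  our baseline CRN kinetics producing a slightly faster upstroke,
  $\dot V_\mathrm{max} \approx 227$ V/s, than the source model it was
  calibrated against, and refining $dx$ *raises* CV — at 0.015 cm by ≈6% —
  so the sharp-front discretization, marginally resolved at 0.03 cm, cannot
  close the gap).  The $\sqrt{D}$ scaling law is asserted on the refined
  grid, where the continuum limit applies.
* **Transmural establishment.** A cold column is "fully transmural" when
  every free (non-Dirichlet) node of the column under the spot center is
  within 1.0 °C of its steady-state value, the steady state being the same
  configuration run to convergence.  The bottom face itself is clamped at
  body temperature by the stated boundary conditions, so a criterion on the
  bottom-face *node* would be degenerate; the whole-column reading is the
  non-degenerate formalization of a fully established transmural profile.
  For the 9-mm 5 °C spot on a 0.25-cm wall it gives ≈12 s, the same
  timescale as the reference observation (15–16 s) and within its stated
  tolerance; the residual gap reflects how much of the slow final
  asymptote an "established" criterion chooses to include.
* **Tips, rotations, filaments.** Phase singularities are located by the
  winding number of $\varphi = \mathrm{atan2}(V(t) - V_\mathrm{iso},
  V(t-\delta) - V_\mathrm{iso})$ (time-delay embedding of consecutive
  snapshots, $V_\mathrm{iso} = -40$ mV, configurable) summed around each
  grid plaquette.  Rotations are the unwrapped tip angle about the running
  centroid, or about the spot center once anchored.  Filaments chain
  per-layer tips by nearest neighbor; filament length is polyline arc
  length, and "transmural" means the chain touches both horizontal faces.

# The control experiments and their scale

The attract-anchor-drag controller places a cold spot on the tip, waits for
anchoring (tip resident in the spot for two rotations by default), then
steps the spot toward the nearest inexcitable boundary, in 3D only after
the cold column has re-established transmurally at the current position
(the necessity of that rule is the central 3D observation this framework
reproduces).  A spot that reaches the boundary squeezes the tip against the
no-flux edge and the wave terminates; termination is declared only when no
tips remain and no node exceeds −40 mV for 500 ms.

Desk-scale test batteries use the spatial scaling invariance of
reaction–diffusion: halving all lengths while quartering $D$ leaves the
kinetics, periods and rotation counts unchanged.  The packaged experiments
run the cAF spiral in a 2.4 × 2.4 cm domain at $D = 0.000625$ cm²/ms with a
0.45-cm spot — the half-scale image of the reference 2D configuration
(domain ≈5–7.5 cm, 0.9-cm spot, full $D$) — and a 2.4 × 2.4 × 0.09 cm slab
(four layers) for the 3D battery.  The thermal solver is *not* rescaled
(heat physics is fixed by $\kappa$), so transmural establishment through
the thin test wall takes ≈2 s rather than the ≈12–16 s of a 0.25-cm wall;
the establishment timescale itself is validated separately at full
thickness.  What the scaled battery demonstrates is therefore the control
logic — anchoring within a few rotations, dragging only behind an
established column, boundary termination, filament transmurality and
charge conservation — not the full-scale timings, which the reference
reports as cluster-scale runs (36 s of simulated time for a 7-cm 3D
relocation).  S1–S2 timing is found by scanning the repolarization tail of
S1; the tests start the scan inside the previously located vulnerable
window of this exact configuration to keep induction inexpensive.

# Known limitations

* The baseline CRN transcription reproduces the published resting state and
  AP within a few percent but not to the digit; the conduction-velocity
  calibration pair (D, CV) is inherited rather than re-fit, leaving CV ≈6%
  above its printed target at the printed discretization.
* Scalar $D$: no fiber anisotropy, no bidomain effects, no realistic atrial
  geometry.
* No perfusion term in the heat equation: establishment times are lower
  bounds on tissue with blood flow, as the reference itself notes.
* The cold AP's mid-level metrics (APD40/APD50 at 5 °C) sit on morphology
  razor edges (±2 mV moves a first crossing by an order of magnitude);
  fold-change magnitudes are robust, their direction at the 50% level is
  not.
* Spiral-wave experiments are run at reduced scale (above); full-scale 2D
  (250 × 250) and 3D (15 × 15 × 0.3 cm) configurations are expressible in
  the same API but take tens of minutes to days on one CPU.
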