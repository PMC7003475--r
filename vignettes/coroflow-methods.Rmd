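---
title: "Methods: reduced-order coronary haemodynamics and wave-free indices"
author: "coroflow developers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: reduced-order coronary haemodynamics and wave-free indices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## What the package computes

Two pressure-derived indices grade the functional severity of a coronary
stenosis in clinical practice. The fractional flow reserve (FFR) is the
cycle-mean of the ratio of pressure distal to the lesion over pressure
proximal to it ($P_d/P_p$), measured under drug-induced maximal hyperaemia,
with treatment indicated below 0.8. The instantaneous wave-free ratio (iFR)
is the same ratio measured at rest, averaged only over the diastolic
"wave-free" period during which no new forward or backward waves are
generated and microvascular resistance is stable; its cut-off is commonly
taken near 0.89. `coroflow` computes both indices (written cFFR and ciFR for
the computed quantities) on 1D coronary tree geometries and provides the
statistical layer — polynomial index relations, Bland–Altman agreement, ROC
with Youden's J — with which a ciFR cut-off equivalent to FFR = 0.8 can be
estimated.

All internal computation is CGS (cm, g, s, dyn/cm²); pressures cross the I/O
boundary in mmHg (1 mmHg = 1333.22 dyn/cm²).

## The 1D model

On each vessel segment the package solves the pressure–flow form of the 1D
haemodynamic equations

$$C_a \frac{\partial P}{\partial t} + \frac{\partial Q}{\partial x} = 0,
\qquad
\frac{\rho}{A}\frac{\partial Q}{\partial t}
 + \frac{\rho}{A}\frac{\partial}{\partial x}\!\left(\frac{Q^2}{A}\right)
 + \frac{\partial P}{\partial x} = -\,\frac{22\,\mu\pi Q}{A^2},$$

with $\rho = 1.05$ g/cm³ and $\mu = 0.04$ P. The viscous coefficient 22
reflects the blunt velocity profiles of coronary flow; its sign is chosen so
that friction opposes flow (the steady limit then reproduces the
Poiseuille-type drop $\Delta P = 22\mu\pi Q L/A^2$, which the test suite
verifies against the time stepper to better than 1%).

The system is closed by a viscoelastic tube law. The elastic part is

$$P - P_0 - P_{ext} = \frac{2\rho c_0^2}{b}\left[\left(\frac{A}{A_0}\right)^{b/2} - 1\right],
\qquad b = \frac{2\rho c_0^2}{P_0 - P_{collapse}},$$

with the reference wave speed taken from the empirical diameter law
$c_0 = \sqrt{\tfrac{2}{3\rho}\left(k_1 e^{k_2 D_0/2} + k_3\right)}$ and
$P_{collapse} = -10$ mmHg. $P_0$ is bound to the state's diastolic pressure
(74 mmHg resting, 70 mmHg hyperaemic). The wall adds a dissipative
viscoelastic stress $\Gamma/(A_0\sqrt{A})\,\partial A/\partial t$ with
$\Gamma = 100D + 400$; inside the solver this term is rewritten via mass
conservation ($\partial A/\partial t = -\partial Q/\partial x$) as an
implicit diffusive flux in the momentum equation, the standard treatment in
P–Q formulations.

**Stiffness constants.** Published variants of the empirical wave-speed
formula differ in scaling; values of order $k_1 \sim 10^1$ g/s²/cm produce
wave speeds of centimetres per second, three orders below physiological.
The package defaults to the literature-scale set $k_1 = 2\times10^7$,
$k_2 = -22.5$ cm⁻¹, $k_3 = 8.65\times10^5$ g/s²/cm (giving $c_0 \approx
7$–$12$ m/s in coronary calibres) and exposes all three as configuration.
An internal-consistency property ties the law together: the linearized
tube-law wave speed $\sqrt{A\,\partial P/\partial A/\rho}$ at $A = A_0$
equals $c_0$ to $10^{-10}$.

### Discretization

A control-volume collocation (staggered) scheme: pressures at cell centres,
flows at faces, one shared pressure node per junction and per terminal.
Mass is conserved per cell by construction; junction rows impose exact flow
balance and static pressure continuity (no junction loss model — stenoses
are resolved through the geometry alone). Time integration is
Crank–Nicolson ($\theta = 0.5$) with Picard iteration of the
area-dependent coefficients evaluated at the half step, giving second order
in both $\Delta x$ and $\Delta t$; the suite measures observed orders
$\ge 1.9$ by Richardson differences on a smooth pulse. The scheme is
implicit (one sparse linear solve per Picard sweep via `Matrix`), so
$\Delta t$ is an accuracy knob, not a stability constraint; the advective
CFL number is nevertheless recorded. Defaults: $\Delta x$ target 0.05 cm,
$\Delta t = 10^{-4}$ s, periodicity declared when cycle-to-cycle pressure
changes fall below $10^{-3}$ (relative). Test and acceptance runs use
deliberately coarser settings ($\Delta x$ 0.1–0.15 cm, $\Delta t$ 1–2 ms) to
fit CI time budgets; with a second-order scheme this costs fractions of a
percent on the indices, and the convergence property is checked at fine
resolution.

Degenerate inputs: the tube law collapses (area $\to 0$) if pressure falls
below $P_{collapse}$; the solver aborts naming the segment and time. Cold
starts of very stiff configurations can trigger this through the startup
water hammer — validation runs therefore warm-start near the expected
steady state.

### Boundary conditions

The root receives a prescribed periodic inflow waveform. Each terminal
carries a five-element coronary bed: $R_a$ into a node with compliance
$C_a^{bed}$, then $R_m$ into an intramyocardial node with compliance
$C_{im}$ biased by the ventricular external pressure $P_{im}(t)$, then $R_v$
to a constant venous pressure (5 mmHg, a population-typical default).
The $P_{im}$ bias reproduces systolic flow impediment — left-tree terminal
flow is diastole-dominant, the phenomenon that motivates iFR — without
changing the cycle-mean flow (the bed is linear). Splits
$R_a:R_m:R_v = 0.32:0.52:0.16$ and compliance time constants
($C_a^{bed} R_{tot} = 0.05$ s, $C_{im} R_{tot} = 0.15$ s) are configurable
defaults of typical lumped coronary beds. Left-side beds use $P_{LV}$,
right-side beds $0.5\,P_{RV}$ (scaling configurable; no established value exists for
the right tree).

Terminal resistances come from the two-tier estimation. The branch total is
$R_i = (\text{systolic}/3 + 2\,\text{diastolic}/3)/Q_i$ with the state's
pressures and the branch's mean inflow; it is distributed over terminals by
Murray's law with power 2.27 on each terminal segment's *proximal*
reference diameter ("proximal Murray's law" is read as proximal-diameter
weighting — an interpretation, recorded here), normalized so the parallel
combination recovers the branch total exactly (to $10^{-12}$, a tested
invariant).

### Tier-1 closed loop

The inflow waveforms and ventricular pressures come from a deliberately
small closed-loop circulation: two time-varying-elastance chambers
(double-Hill activation, systolic fraction 0.3 at rest shortening with
heart rate by a square-root law), systemic and pulmonary Windkessel
compartments, and two aggregate coronary branches. The loop is
volume-conserving by construction (every flow appears once with each sign),
so RK4 preserves total volume to round-off. Calibration is a damped
deterministic fixed point with three knobs for three targets: systemic
resistance → pressure level, arterial compliance → pulse pressure,
circulating volume → cardiac output; it stops when systolic, diastolic and
cardiac output are within 2% of the state's targets (115/74 mmHg, 5.19
L/min, HR 65 resting; 115/70, 7.6, HR 90 hyperaemic).

The hyperaemia transform multiplies the coronary *bed* resistance by
exactly 0.22 (a 78% reduction), switches the heart rate, and recalibrates
to the hyperaemic column — reduction first, recalibration second (the
ordering is a design choice here; doing both sequentially keeps the
aortic targets exact). Each coronary branch is modelled as an epicardial
conduit resistance (8% of the branch total at rest, *not* recruited by
hyperaemia) in series with the microvascular bed (92%). This is the
standard physiological explanation for why measured hyperaemic/resting flow
ratios (~3.5) fall short of the pure-bed prediction $1/0.22 = 4.5$: with a
conduit fraction $f$, the ratio is $\approx (MAP_h - P_v)/(MAP_r - P_v)
\cdot 1/(f + (1-f)\times 0.22) \approx 3.4$–3.5 for $f = 0.08$. The value
was chosen from that physiology before any simulation was run. Total
coronary flow at rest is 4% of cardiac output, split 70/30 left/right
(population-typical; recorded in metadata). Exactly two waveform pairs
exist per configuration and are cached and reused by every case.

### Indices

cFFR is the mean of the *instantaneous* ratio $P_d/P_p$ over the final
converged hyperaemic cycle — mean of ratio, not ratio of means (the
difference is below 0.005 in smooth cases but the convention is fixed).
ciFR averages the same ratio over the wave-free window of the resting run,
which opens one fifth of the way into diastole and closes at the cycle end:
$t_{start} = t_d + 0.2(T - t_d)$, $t_{end} = T$, with $t_d$ the aortic
valve closure time exported by the closed loop (a dicrotic-notch detector
is available as a fallback for external traces). The proximal probe sits at
the tree inlet; the distal probe 1 cm or three throat diameters (whichever
is larger) beyond the most distal throat, clamped to the segment — probe
placement is configurable and recorded, since the clinically exact
measurement point is unknown. Forward/backward wave separation uses the
linearized characteristics $dP_\pm = (dP \pm \rho c\, dU)/2$, which
reconstruct $dP$ exactly by construction.

## Synthetic geometry

No clinical geometries accompany the method, so the generator emulates
segmented CCTA centreline output: rooted binary trees of 5–30 tapering
segments, root diameters 0.15–0.6 cm, lengths drawn uniformly from 1–8 cm
shrinking by 0.72 per generation, taper 0.85–1.0, daughter asymmetry
0.7–1.0, and daughter diameters satisfying the generalized Murray relation
$d_p^\gamma = \sum d_k^\gamma$ (default $\gamma = 2.27$) exactly at every
junction. Stenoses are superimposed multiplicatively on the reference area:
a C¹ cosine bell for focal lesions, a flat-throat trapezoid for diffuse
disease. What the generator does **not** emulate: lumen eccentricity and
irregular plaque geometry, image noise and calcium blooming, serial-lesion
correlation structure, side branches below the segmentation threshold.
A green test therefore establishes correctness of the solver, the boundary
assignment and the index definitions on smooth tree geometries — not
image-pipeline fidelity on clinical anatomies, and not reproduction of the
original clinical cohort's patient-level numbers (such data are not publicly available; the
statistics layer is instead verified on cohorts generated from the
published quadratic ciFR–cFFR relation with Gaussian noise, SD 0.005).

## Statistics layer conventions

Positivity is *strict* value < threshold (a value exactly at the cut-off is
negative); the ROC sweeps thresholds over the observed values plus
sentinels, computes AUC by trapezoid (identical to the Mann–Whitney
statistic, a tested identity), and picks the optimum by Youden's
$J = \text{sens} + \text{spec} - 1$ with ties broken toward the higher
threshold. Both choices are conventions with no single standard; they are
fixed and documented here. Polynomial relations are ordinary least squares
of degrees 1–3; the ciFR threshold equivalent to FFR = 0.8 is the fitted
polynomial evaluated at 0.8. Display rounding: 4 decimals for indices and
thresholds, 2 for percentages.

## Known limitations

- No coronary autoregulation (deliberately excluded, matching the method's
  stated scope) and no stenosis loss submodel beyond the resolved geometry;
  very short/abrupt lesions are therefore resolution-sensitive.
- The tier-1 loop is a calibrated stand-in: it meets the stated pressure,
  output and flow-ratio targets but does not reproduce any particular
  patient's waveform morphology.
- Mean of instantaneous pressure ratios is ill-conditioned if $P_p$
  approaches zero; physiological inputs keep $P_p$ far from zero and the
  code errors rather than returning a silent NaN.
- The implicit scheme trades per-step cost for unconditional stability;
  R-level assembly makes very fine meshes (thousands of cells) slow — the
  intended regime is tens to hundreds of cells per tree.
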