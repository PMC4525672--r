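---
title: "A quasi-static model of air-mucus interaction during chest physiotherapy"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A quasi-static model of air-mucus interaction during chest physiotherapy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`bronchosim` simulates what a chest-physiotherapy maneuver does to airway
secretions. The input is a time-varying pressure applied homogeneously on the
chest; the outputs are the deformation of the bronchial tree, the air flow
that the deformation drives, the redistribution or expulsion of a
yield-stress mucus layer, and scalar efficiency and comfort measures. This
vignette explains the model, its assumptions, the numerical scheme, and the
choices made where the design was genuinely open.

## The lung

The bronchial tree is an idealized symmetric dyadic tree with 23 generations
(trachea = generation 0). Generations 0–16 are conducting airways whose
lengths and reference diameters come from the classical morphometric tables
shipped in `inst/extdata/lambert_airways.csv`; generations 17–22 are the
acini: alveolar ducts of fixed length 0.7 mm, each carrying 58 of the lung's
480 million alveoli. The lung is scaled to TLC 6.5 L, VC 5 L, RV 1.5 L; FRC
sits at 35% of VC above RV, hence 3.25 L.

All airways of a generation are identical, so the state reduces to
per-generation quantities. Lumen areas are carried *generation-summed* (the
area constants `A_m` are the total over the `2^z` airways of generation `z`);
per-airway values divide by `2^z`. A per-airway maximal area of 180 cm² at
generation 16 would be physically impossible, and the generation-summed
reading reproduces the printed tree volumes, so this interpretation is built
into the package.

## Static mechanics

**Conducting airways.** Each generation follows a sigmoid transmural
pressure–area law

$$ S_z(\Delta P)=\begin{cases}
\alpha_0\,(1-\Delta P/P_1)^{-n_1} A_m & \Delta P\le 0\\[2pt]
\left(1-(1-\alpha_0)(1-\Delta P/P_2)^{-n_2}\right) A_m & \Delta P> 0
\end{cases} $$

with $P_1=\alpha_0 n_1/\alpha_0'$ and $P_2=-n_2(1-\alpha_0)/\alpha_0'$. The
law is C¹ at $\Delta P=0$ (value $\alpha_0A_m$, slope $\alpha_0'A_m$) and
increases from 0 to $A_m$. The distending transmural pressure is
$P_\mathrm{tissue}(V_L)-P^{(z)}_\mathrm{air}$, with the tissue pressure a
function of lung volume only. The exponent sign on the inflating branch is
taken negative (the standard form); the positive reading diverges and is
rejected.

**Acini.** An alveolar-duct unit (one duct plus its 58 alveoli) takes the
volume the whole relaxed respiratory system would have under its local
airway-to-chest pressure difference, minus the tracheobronchial volume in
that relaxed configuration, divided by the number of duct units
($2^{17}\times 63$). A fixed fraction $\alpha=0.17$ of the unit volume is
duct lumen; the rest is alveolar.

**Lung volume.** $V_L$ solves the scalar fixed point
$V_L=V_\mathrm{ac}+V_\mathrm{tbt}(V_L)$, by safeguarded Newton iteration.
The tracheobronchial slope in $V_L$ stays well below one under the default
curves, so the fixed point is unique.

### Reconstructed pressure–volume curves

The respiratory-system volume curve and the tissue-pressure curve are not
tabulated anywhere; only anchors are available. The package uses closed
forms:

* volume: logistic, $V(\Delta P)=RV+VC/(1+e^{-(\Delta P-P_h)/P_s})$,
  calibrated so that $V(0)=\mathrm{FRC}=3.25$ L and so that a quasi-static
  −5 cmH₂O chest depression produces exactly the 0.5 L rest tidal volume.
  The implied rest compliance is 0.095 L/cmH₂O (≈ 0.1 L/cmH₂O).
* tissue pressure: exponential recoil,
  $P_t(V)=A\,(e^{k(V-RV)}-1)$, anchored at FRC and at TLC
  (30 cmH₂O).

**The FRC anchor.** Two statements about the rest transmural pressure
coexist in the source material: a nominal "about 500 Pa", and the tabulated
reference diameters, which all 17 generations match the sigmoid laws at
50 ± 1 Pa. The canonical FRC volume decomposition (bronchial tree 0.67 L,
alveoli 2.58 L, single-alveolus volume 5.37·10⁶ μm³, diameter 217 μm,
exchange surface ~70 m²) is reproduced exactly by the Table-1 reference
geometry itself, so it cannot discriminate between the two anchors. The
dynamics can: with a 50 Pa anchor the lung retains almost no recoil under
strong chest compressions, mid-tree airways collapse onto their
incompressible mucus, gas is trapped, and the documented maneuver
behavior (large tidal compressions, falling tree resistance, mucus
expulsion above a pressure threshold) disappears. The package therefore
anchors at 500 Pa by default and exposes the diameter-consistent
alternative as `table1_transmural()`. With the 500 Pa anchor the
Lambert-law tree volume at rest is 0.71 L (6% above the reference
geometry's 0.67 L) — the price of the contradiction. Both curves may also
be replaced by user-supplied monotone tables; these reconstructions are the
main source of quantitative deviation from the reference results.

## Air and mucus hydrodynamics

Air (Newtonian, μ = 1.8·10⁻⁵ Pa·s) flows in the circular core of each
airway; mucus (Bingham: rigid below the yield stress σ₀ = 0.1 Pa, viscosity
0.1 Pa·s above it) forms a concentric annulus against the wall. Under a
uniform axial pressure gradient $C$, the shear stress is $\tau=Cr/2$, so the
annulus is rigid wherever $r<r_0=|2\sigma_0/C|$:

* $r_0\ge r_b$: the annulus is a rigid sleeve; air is Poiseuille flow in the
  core and the mucus flux is exactly zero (the yield dead-zone);
* $r_a<r_0<r_b$: a rigid plug attached to the interface rides on a sheared
  layer against the wall;
* $r_0\le r_a$: the whole annulus is sheared.

Velocity profiles integrate in closed form in all three regimes, giving both
fluxes and a piecewise-analytic inverse (linear / quadratic root / linear)
from air flux back to the gradient. A numerical-quadrature oracle
(`profile_oracle()`) validates the closed forms to better than 10⁻⁷ relative
error in the test suite; it is never used by the stepper. A
`rigid_interface` variant that holds the air-mucus interface still is
available for sensitivity analysis; with a viscosity ratio of 5.6·10³ the
coupling correction is small.

Fluxes are signed positive down the tree, so mucus moving toward the mouth
has negative flux; the trachea's negative mucus outflow accumulates into the
expelled volume. Between generations, mucus inflow follows the printed
routing rule: a parent's down-tree outflow splits in half over the two
daughters, a daughter's up-tree outflow counts twice into the parent, and
flows of the opposite sign do not account. Mucus cannot enter the acini:
the generation-16 outflow is clamped non-positive.

## Time integration

The unknown of each backward-Euler step (dt = 5·10⁻³ s, resolving a 20 Hz
oscillation with 10 steps per cycle) is the 23-vector of mid-airway
pressures. A candidate pressure vector determines the lung volume (inner
scalar Newton solve), the bronchus areas and alveolar volumes; backward
differences give the air flows by a leaf-to-root recursion
$\Phi^{(z)}=\dot S_a^{(z)}l_z/2^z+2\Phi^{(z+1)}+58\,\dot v_\mathrm{alv}$;
the closed-form inverse maps flows to gradients; and accumulating
$C^{(z)}l_z$ from the atmospheric trachea reference yields the pressures the
candidate must reproduce (with the ½ term placing each pressure at
mid-airway length). A damped chord Newton (finite-difference Jacobian reused
across steps, refreshed adaptively, full Newton with per-iteration Jacobians
as a second phase) drives the residual below 10⁻⁴ Pa.

Mucus areas update from end-of-step fluxes and are iterated to
self-consistency within the step (fully implicit mode, the default);
outflows are capped by the mucus present in the airway, which keeps the
tree-plus-expelled mass balance exact to machine precision even when an
airway runs dry. Air lumen radii are floored at 1% of the bronchus radius
inside the flux closed forms.

### Two numerical safeguards

Two behaviors of the strictly quasi-static system require care:

* **Incompressible mucus supports the wall.** When compression drives the
  static lumen area below the mucus area, the bronchus cannot actually crush
  the liquid: the effective lumen is floored at the mucus area plus the
  floored air core. Without this the update would have to discard mucus
  volume.
* **Airway-collapse folds.** During strong compressions the feedback loop
  (narrowing raises the local pressure drop as $r_a^{-4}$, which lowers the
  transmural pressure downstream, which narrows further, amplified by the
  per-step rate $1/\mathrm{d}t$) can exceed unit gain, and the implicit
  system of a full-size step *provably loses its root*: independent
  Levenberg-Marquardt minimization from many starting points lands on the
  same strictly positive residual floor. The package regularizes this with a
  short viscoelastic wall relaxation: conducting areas track their static
  law through a first-order implicit filter with time constant `wall_tau`
  (default 20 ms). Equilibria are unchanged, the scheme stays first-order,
  and the acinar mechanics remains strictly quasi-static. Residual steps
  that still stall do so on floors below `newton_tol_fallback` (0.02 Pa,
  against ~2000 Pa forcing) and are counted in the run diagnostics
  (`n_soft`, `n_forced`, `max_resid`), so any trajectory can be audited.
  A trapped-gas predictor (pressures tracking the chest pressure one for
  one, the exact limit behind a mucus plug) provides the second Newton
  starting point at plugging events.

## Maneuvers

All maneuvers ride on quiet ventilation,
$P_\mathrm{ext}(t)=P_v\,(1-\cos(2\pi t/5))/2$ with $P_v=-5$ cmH₂O (period
5 s). Within the 230-s session (10 s quiet lead-in and tail):

* manual chest physiotherapy adds $P_{cp}\max(\sin(2\pi t/5),0)$ — positive
  pressure on the expiratory half-cycles, phase-locked to the global clock;
* high-frequency chest wall oscillation adds $P_s+(P_o/2)\sin(2\pi f t)$;
  chest-compression devices use a static term $P_s>0$, focused-pulse
  devices are represented by their equivalent oscillation amplitude alone.

The maneuver term is multiplied by a linear ramp over 10–15 s and 215–220 s
for both families (the manual term vanishes at those window edges anyway,
since they fall on zeros of the sine).

## Initial mucus distribution

The default fixture fills 10% of each lumen over generations 0–5, rises
through generations 6–7 (0.20, 0.35) to a 50% peak at generation 8, then
decays to zero at generation 16. The decay values follow a power law whose
exponent (1.486) was pinned once so that the rest-state mean mucus position
equals 7.34 — the single quantitative anchor available for the
distribution — and then frozen as constants. The distribution is
deliberately at the margin of immobility: quiet breathing leaves it exactly
unmoved (the yield dead-zone is never crossed), while manual pressures
above roughly 16–17 cmH₂O start expelling mucus from the trachea.

## Outcome metrics

* **Expelled volume** `v_out`: cumulative mucus through the trachea's mouth
  end.
* **Relative resistance** `r`: Poiseuille air-core resistance of the
  conducting tree (series across generations, `2^z` airways in parallel),
  evaluated on an FRC-referenced configuration — rest-state bronchus areas
  with the *current* mucus volumes — and normalized by its pre-maneuver
  value, so r(0) = 1 by construction. An instantaneous variant is also
  computable from the recorded traces.
* **Mean mucus position** `mmp`: mucus-volume-weighted mean generation
  index; the expelled volume enters the numerator with weight −1 (implemented
  literally as defined, which effectively places expelled mucus at
  generation −1).
* **Shrek number**: the average over the 17 conducting generations (the
  mucus-bearing part of the tree; `N` is configurable) of the air shear
  stress $4\mu_a|\Phi|/(\pi r_a^3)$ over the yield stress σ₀, with $r_a$ the
  current air-lumen radius — the shear acts at the air–mucus interface. The
  resistance-based approximation $R_\mathrm{aw}|\Phi_\mathrm{mouth}|/(12N\sigma_0)$
  is exact for length-to-diameter ratios of 3 and is reported alongside.
  The session value is the trapezoidal time average.
* **Comfort number**: time-averaged absolute relative shift of the tissue
  pressure against a ventilation-only run on the same grid; zero for pure
  ventilation, large for sustained compressions.

## Problem sizes and determinism

Everything is deterministic — there is no randomness anywhere in the
simulator. The bundled analyses use 25-s ventilation runs (5,000 steps) for
tidal volume and Shrek baselines and full 230-s sessions (46,000 steps) for
the manual-physiotherapy outcomes; the threshold search stops a run as soon
as the first mucus leaves the trachea.

## Known limitations

* The pressure on the chest is homogeneous; localized hand placement,
  asymmetric branching, and flow asymmetries are out of scope.
* Air inertia, turbulence and oscillatory (Womersley) profile corrections
  are neglected; profiles are fully developed Stokes flow.
* Mucociliary clearance and cough are absent; mucus is a homogeneous
  Bingham layer of uniform thickness along each airway.
* The pressure-volume curves are reconstructions from printed anchors, not
  measured curves; quantitative outputs (final resistance, expulsion
  threshold) inherit that uncertainty, and passing tests demonstrate
  internal consistency under these reconstructed conditions rather than
  fidelity to any individual patient.
* The wall-relaxation regularization (20 ms) slightly smooths
  airway-collapse transients; `wall_tau = 0` recovers the strictly
  quasi-static system wherever it is solvable.
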