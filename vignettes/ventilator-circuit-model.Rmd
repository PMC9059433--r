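---
title: "The ventsim model: physics, parameters, and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The ventsim model: physics, parameters, and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ventsim)
```

ventsim is a desk-scale simulator of the breathable-air circuit of an
electro-pneumatic volume-controlled ventilator (VCV): a regulated gas source
feeding a rigid patient tube through a gating valve, the tube feeding a
single-compartment compliant lung, and an exhalation valve venting the tube
to atmosphere during expiration. This vignette is the package's account of
the model itself: its equations and assumptions, the parameters that matter
and why their defaults are what they are, and the numerical decisions made
where the design was genuinely open.

## Model assumptions

Three assumptions define the scope of the physics:

1. **Ideal gas.** Every chamber obeys $pV = mR\theta$ with the specific gas
   constant $R$ of dry air.
2. **Isothermal, quasi-static thermodynamics.** The working temperature
   $\theta$ is constant; filling and emptying are slow enough that no
   temperature dynamics are tracked.
3. **No leakage.** All gas crossing a chamber boundary passes through a
   modelled valve, so stored mass must balance integrated boundary flow
   exactly; the integrator reports this residual on every run.

Pressures are **absolute pascals** inside the physics core. Clinical and
engineering units (cmH2O, kPa, MPa, mL, L/min, mm²) exist only at the
configuration and output boundaries, with 1 cmH2O = 98.0665 Pa exactly. This
split exists because compressible-flow formulas involve absolute pressure
*ratios* while clinicians think in gauge cmH2O; mixing the two silently is
the classic failure mode of this kind of model.

## Compressible orifice flow

Every valve is an effective orifice of area $A$. With upstream/downstream
absolute pressures $p_u > p_d$ and $r = p_d/p_u$, the mass flow is the
standard converging-nozzle law:

$$
\dot m =
\begin{cases}
A\,p_u\sqrt{\dfrac{k}{R\theta}}\left(\dfrac{2}{k+1}\right)^{\frac{k+1}{2(k-1)}}
 & r \le b \quad\text{(choked)}\\[2ex]
A\,p_u\sqrt{\dfrac{2k}{(k-1)R\theta}}\sqrt{r^{2/k}-r^{(k+1)/k}}
 & r > b \quad\text{(subsonic)}
\end{cases}
$$

with the critical ratio $b = \left(2/(k+1)\right)^{k/(k-1)}$, which is 0.528
for air ($k = 1.4$). The two branches join continuously at $r = b$, choked
flow is independent of downstream pressure, and flow is exactly linear in
area — all three are enforced as property tests. The law returns a
magnitude; the circuit graph assigns direction (high to low pressure), which
keeps the formula single-signed.

## Chambers: rigid tube, compliant lung

The tube is a rigid isothermal chamber of volume $V_t$:

$$\frac{dp_t}{dt} = \frac{R\theta}{V_t}\left(\dot m_{in} - \dot m_{tl} - \dot m_{ex}\right)$$

The lung is a linear single-compartment balloon: volume responds to gauge
pressure with constant compliance $C_l$,

$$V_l(p_l) = V_{l0} + C_l\,(p_l - p_{atm}),$$

and combining the ideal-gas mass balance
$d(p_l V_l)/dt = R\theta\,\dot m_{tl}$ with $dV_l/dt = C_l\,dp_l/dt$ gives

$$\frac{dp_l}{dt} = \frac{R\theta\,\dot m_{tl}}{V_l(p_l) + C_l\,p_l}.$$

Setting $C_l = 0$ recovers the rigid-chamber form, which is the consistency
check the implementation is tested against. Compliance is deliberately
linear and constant — no recruitment or overdistension curvature — because
the model this package implements states it as a constant derivative and
reports linear volume–pressure behaviour in the regime of interest. All
airway resistance is lumped into the valve orifice areas; there is no
separate resistive element and no inertance.

## The volume controller and the breath cycle

During inspiration the ventilator is an ideal flow source at the set flow

$$Q_T = \frac{V_T}{T_i - T_p},$$

delivering until the volume delivered this breath reaches $V_T$, after which
output is zero (volume-triggered cutoff). The cycle is partitioned half-open
into INSPIRATION $[0, T_i-T_p)$, PLATEAU $[T_i-T_p, T_i)$, EXPIRATION
$[T_i, T_i+T_e)$ and REST for any remaining slack, during which all valves
are closed. If the volume cutoff and the inspiratory-time cutoff disagree,
the earlier event wins and the remainder of $T_i$ is plateau — the
controller is volume-triggered, so this tie-break preserves the delivered
volume, not the timing.

The flow-source idealization is bounded by physics: the commanded mass flow
is capped at the compressible-flow capacity of the supply orifice at the
regulated source pressure and the instantaneous tube pressure. If the cap
binds, the breath is flow-limited and the run log says so. This cap is also
what makes the "wide-open, long inspiration" limit behave correctly: the
lung equilibrates at the source pressure, taking up $C_l(p_{src}-p_{atm})$.

## Valve archetypes and the relay circuits

Three solenoid-valve archetypes gate the circuit, each a small state
machine over positions with a fixed connectivity table:

| archetype | positions | return | home connectivity |
|---|---|---|---|
| 5/2 (alias PA) | HOME, ACTUATED | bistable, two coils | exhaust open |
| 5/3 (alias PB) | HOME, MID, ACTUATED | spring | supply open |
| 3/2 (alias PC) | HOME, ACTUATED | spring | exhaust open |

The 5/2 has memory: a sole energized coil drives it (after the switching
delay); both coils or neither retain the position, because opposed coils
act with equal force. The 5/3 and 3/2 spring home when de-energized; the
5/3's home side is the pressurised one, matching a circuit whose rear
chamber is filled in the initial position and exhausted when the coil
energizes. The 5/3 additionally gets a "magnetic cushion" option (on by
default for that archetype): the exhaust area opens as a first-order lag
with a 0.2 s time constant instead of instantaneously, the minimal model of
a slow-start mechanism that removes the impulsive kick at the start of
exhaust.

The rig control circuits are emulated as a relay ladder: a latched
pushbutton energizes relay K1, K1 feeds an on-delay timer, and the timer
output re-arms itself so the solenoid command toggles every $d$ seconds —
actuation alternates with period $2d$. The on-delay timer itself has the
textbook semantics: output true iff the input has been continuously true
for at least the delay, reset on a falling edge. The twelve rig presets
(`PA1`–`PC4`) cross the three archetypes with timer settings 10/12/14/16 s.
Whether those settings are half-periods or full periods of the toggle was
an open choice; they are used as **half-periods** (the valve toggles at
$t = d, 2d, 3d, \dots$), which matches a ladder in which the timer re-arms
on firing. A property test pins the equivalence: the circuit-driven phase
sequence equals the timed phase machine with $T_i = T_e = d$.

The clinical breath timing grid (exhaust times 1.0–1.8 s) and the rig
timer grid (10–16 s) are kept as two scenario *families* rather than forced
into one cycle model, because they describe different experiments: `breath`
scenarios use the clinical settings directly; `rig` scenarios derive
$T_i = T_e = d$ from the timer.

## Parameters and defaults

All defaults are config-overridable; these are the study conditions the
package ships with.

| parameter | default | unit | rationale |
|---|---|---|---|
| $R$ | 287.05 | J/kg/K | dry air standard |
| $k$ | 1.4 | — | dry air; gives $b = 0.528$ |
| $\theta$ | 293.15 | K | room temperature, isothermal |
| $p_{atm}$ | 101325 | Pa | standard atmosphere |
| $V_T$ | 500 | mL | mid-range adult tidal volume |
| $T_i$ | 1.2 | s | clinical inspiratory time |
| $T_p$ | 0.3 | s | end-inspiratory pause; comfortably longer than the 0.2 s plateau-detector window so a true pause is detectable |
| $T_e$ | 1.6 | s | reference exhaust setting |
| cycle | 4 | s | 15 breaths/min |
| $C_l$ | 0.05 | L/cmH2O | ventilated-adult respiratory compliance |
| $V_{l0}$ | 2.0 | L | adult FRC-scale unstressed volume |
| $V_t$ | 0.5 | L | patient-circuit internal volume |
| $A_{ev}$ | 6 | mm² | exhalation-valve effective area (bench value) |
| $A_{rt}$ | 12 | mm² | tube→lung path; sized so the drive pressure at the default set flow is ~11 cmH2O, keeping peak tube pressure inside the 0–40 cmH2O clinical envelope |
| $A_{sup}$ | 6 | mm² | supply orifice; choked capacity ≫ set flow at the default source |
| $p_{src}$ | 200 | kPa abs | typical regulated drive pressure |

Plateau detection defaults: slope tolerance `eps` = 0.5 cmH2O/s sustained
for `tau` = 0.2 s; the detector returns the earliest maximal interval and
its mean pressure, and absence is a valid result. The monotone
plateau-vs-exhaust-time property is insensitive to these values over an
order of magnitude. Metrics are read from the last simulated cycle after a
washout of 2 cycles (3 simulated by default), since the early cycles of a
short-exhaust scenario still accumulate end-expiratory pressure.

## Numerical choices

**Integration.** Each breath phase is integrated as its own `deSolve::lsoda`
segment, so valve switching discontinuities are segment boundaries rather
than something the step controller must smear across. The tidal-volume
cutoff is located by `lsodar` root-finding on the delivered-volume state
inside the inspiration segment. Default tolerances are `rtol` $10^{-8}$,
`atol` $10^{-10}$ in internal units; a regression test checks that halving
them moves peak pressure by less than 0.1%.

**Regularized equalization.** The subsonic law behaves like
$\sqrt{1-r}$ near $r = 1$, which is non-Lipschitz exactly where two chambers
equalize — a finite-time contact that stalls adaptive integrators. Below a
5 Pa (~0.05 cmH2O) pressure difference the flow is taken linear in
$\Delta p$, continuous at the band edge. The band is three orders of
magnitude below any feature the model resolves; its visible effect is that
final equalization is exponential rather than finite-time, far below the
plateau detector's threshold.

**Mass bookkeeping.** Cumulative boundary masses are carried as integrator
states, so the conservation residual (stored-mass change minus net boundary
flow, as a fraction of throughput) measures integrator error only; runs
report it in the log and tests bound it at 0.5%.

**Determinism.** The model has no stochastic component; identical
configurations produce bit-identical waveform CSVs, which is tested.

## What the scenarios do and do not emulate

The scenario generator reproduces the *structure* of the bench experiments:
the tidal-volume grid 300/500/600/700 mL, the exhaust-time grid 1.0–1.8 s,
the 6 mm² exhalation valve, and the twelve archetype × timer rig presets.
It does not reproduce the bench rig's absolute outputs, because the rig's
tube volume, lung compliance and drive pressures are not published; the
tabulated bench pressures are in the MPa range, three orders of magnitude
above any clinical airway pressure, and are treated as qualitative trend
targets only. What passing tests show is therefore: the physics core is
correct against closed forms and oracles, conservation holds, and the
qualitative trends (peak pressure rising with tidal volume; the pressure
platform appearing only when exhaust time is long enough) are reproduced —
not that any particular bench number is matched.

Two desk-scale consequences are worth stating explicitly:

**Exhaust-time threshold.** With the defaults above, blow-down of a 500 mL
breath through the 6 mm² exhalation valve settles in roughly 4 s (the
finite-time estimate $t \approx 2\sqrt{V_T C_l\,p_{atm}/(2R\theta)}/A_{ev}$
gives ~4.3 s), so across the clinical 1.0–1.8 s exhaust grid the platform is
absent throughout and end-expiratory pressure accumulates (auto-PEEP) — the
monotone trend holds, but the transition to "platform present" sits near
4–6 s, not at 1.6 s. The bench threshold depends on the unpublished rig
mechanics; the package asserts the trend, never the threshold. A test
extends the grid to longer exhaust times to exercise the genuine
absent→present transition.

**Compliance-recovery bias.** The standard static-compliance identity
$C_{est} = V_T / (P_{plat} - PEEP)$ carries an irreducible gas-compression
bias in any circuit model: equilibrating the delivered gas across tube and
lung gives

$$C_{est} = C_l + \frac{V_t + V_{l0} + C_l\,\Delta p}{p_{atm}},$$

an overestimate of about 2.4 mL/cmH2O with the default volumes — the
desk-scale version of the "compressible volume loss" correction familiar
from real circuits. The recovery check therefore uses a grid where the
manoeuvre is valid as a measurement: compliances 0.07–0.10 L/cmH2O (normal
adult range, where the bias is under 5%) crossed with lung-protective tidal
volumes 300–500 mL, with a long exhaust so PEEP is near zero. At the stiff
default of 0.05 L/cmH2O the bias alone is ~6%, which is a property of the
estimator, not an implementation error.

## Known limitations

- Single lung compartment, linear compliance, no airway inertance, no
  patient effort, no gas exchange, no humidity or FiO2-dependent gas
  properties.
- All resistance is lumped into valve effective areas; there is no
  separate endotracheal-tube resistance element.
- Valve switching is positionally discrete (instantaneous after the
  switching delay), except for the 5/3 cushion ramp.
- Volume-controlled ventilation only: no pressure-control, assist, SIMV or
  proportional modes.
- The bench tables' absolute MPa-range pressures and paired
  volume–time grids are out of scope by design; only trends are compared.
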