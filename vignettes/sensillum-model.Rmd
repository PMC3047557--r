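---
title: "An electrical-circuit model of the moth pheromone-sensitive sensillum"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{An electrical-circuit model of the moth pheromone-sensitive sensillum}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sensillum)
```

## The system and the model

Moth pheromone-sensitive sensilla are hair-like cuticular organs housing the
long outer dendrite of an olfactory receptor neuron (ORN) bathed in sensillar
lymph, with the inner dendrite and soma in the hemolymph and a group of
auxiliary cells separating the two media. Two potentials summarize the
organ's response: the **receptor potential** (RP), the stimulus-induced
change of the ORN's transmembrane potential, and the **sensillar potential**
(SP), the change of the lymph potential recorded at the cut hair tip — the
experimentally accessible quantity, of opposite sign to RP.

`sensillum` implements this organ as an electrical network:

* the 220-µm outer dendrite is discretized into `N` isopotential
  compartments (default `N = 40`). Each compartment has a membrane
  capacitance, a leak branch (conductance `g_ldc`, battery `E_ld`), and
  pheromone-dependent branches; adjacent compartments are linked by
  intracellular (`g_ic`) and lymph (`g_ec`) axial conductances;
* the inner dendrite and soma are one compartment (capacitance `C_s`, leak
  `G_ls`/`E_ls`, plus a Ca²⁺- and voltage-gated K⁺ branch);
* the auxiliary cells are one compartment (capacitance `C_a`, branch
  `G_a`/`E_a`) whose battery generates the transepithelial potential (+35 mV
  lymph vs. hemolymph at rest);
* the hair tip is sealed on both wires — the recording electrode is treated
  as ideal (infinite impedance), so no current leaves through the tip.

Transmembrane current is positive outward throughout; depolarizing
pheromone-gated currents are therefore negative. Because the batteries
satisfy `E_ld = E_ls + E_a`, the resting state carries zero current in
every branch, and RP and SP are exactly zero without stimulation.

Two model variants share this circuit:

* the **complete model** gates four outer-dendritic currents with Hill
  kinetics — an IP₃-gated Ca²⁺ current, a DAG-gated cationic current, a
  Ca²⁺-gated Cl⁻ current and a Na⁺/Ca²⁺-exchange (NCX) current — with
  feedback inhibition (CaCaM raises the Ca²⁺/cationic EC50s, PKC\* the Cl⁻
  EC50) and a per-compartment Ca²⁺ mass balance;
* the **simplified model** replaces the four currents of each compartment by
  a single equivalent branch with conductance `g_p_j(t)` and battery
  `E_p = 0` and removes the K⁺ current, so repolarization is carried by the
  leak conductances alone.

The two are linked exactly: dividing the summed pheromone-dependent current
of a complete-model run by the instantaneous driving force (`lumped
conductance`, see `replay_conductances()`) and replaying it through the
simplified circuit reproduces the complete model's potentials at every
compartment and time. The replay carries the soma K⁺ conductance series
along for the soma node to match as well; the default simplified model
remains K⁺-free.

## State reduction and integration

The capacitances sit across the membranes only, so the independent dynamic
states are the `N` transmembrane potentials `u_j = V_id_j − V_ed_j`, the
soma potential and the auxiliary node potential. The individual wire
potentials follow from an algebraic Kirchhoff constraint (the axial inflows
of the two wires must carry equal and opposite membrane current), a constant
tridiagonal system factored once per model. This reduction keeps the ODE
system small (`N + 2` electrical states; `4N + 3` with the transduction
states) and avoids a differential-algebraic formulation.

Integration uses `deSolve::lsoda` with `rtol = 1e-6`, `atol = 1e-9` and a
1-ms step cap by default — an adaptive solver matching the non-stiff
character of the electrical problem, with automatic stiff fallback built
into `lsoda` itself. Conductance steps and square pulses are integrated
segment-by-segment across their switch times so discontinuities are never
stepped over. Outputs are sampled on a uniform grid (default 1 ms) or on a
caller-supplied grid; resolving the millisecond-scale electrical transients
requires a grid of 20–100 µs around switch times, as used in the tests.

## Closed-form cable solutions as oracles

For a maintained uniform conductance the steady state has a closed form.
With both wires sealed at the tip the total longitudinal current vanishes
everywhere, reducing the two-wire cable to one equation for the
transmembrane potential `W(x)`:

`W'' = (1 + g) W − (E_ld + g E_p)`, with `g = r_ld g_p` the
pheromone-dependent conductance in units of the resting membrane
conductance and `x` in space constants. Hence `W(x) = W_inf + A cosh(qx)`
with `q = sqrt(1 + g)`, and the lumped base load (soma and auxiliary
resistances and batteries in series) fixes
`A = (E_ls + E_a − W_inf) / (cosh(q l_d) + r_in q sinh(q l_d))`. RP along
the dendrite, RP at the soma and the tip SP follow (`steady_rp_profile()`,
`steady_rp_soma()`, `steady_sp()`). With `E_p = 0` the ratio SP/RP is
independent of every battery — it depends only on `r_e/(r_e + r_i)`, the
auxiliary fraction `a` and `l_d` — and is therefore dose-independent, about
−1/3 at the dendrite base with the bundled parameters.

These closed forms were *reconstructed from the boundary-value problem*, not
transcribed, and are certified by an independent fine-grid compartmental
solve (`N = 2000`, agreement better than 0.05%) in the test suite. The
published convergence behavior is reproduced: at `G_p = 5` nS the `N = 1`
model errs by ~19% against the analytic base RP and the `N = 40` model by
less than 1% for both RP and SP, which motivates the default `N = 40`.

For transients, `transient_small_signal()` implements the cosine-series
solution of the linearized cable equation on a sealed-sealed cable whose
sensory span `[0, l_d]` receives a uniform conductance step. Two
approximations are inherent: the `g·v` term is dropped (valid for total
steps up to ≈0.2 nS), and the lumped base load is replaced by a passive
cable extension. Because the actual load is nearly matched
(`1/r_in ≈ 1.08` times the characteristic conductance), the default
extension is long (three space constants), whose input conductance
approaches the characteristic value; a short stub (e.g. the ≈30 µm
non-sensory neurite alone) is nearly an open circuit and misses the steady
level severalfold. Even with the matched-length choice the two
approximations together floor the worst-case deviation from the `N = 40`
numerical step response at about 20% at 0.2 nS, concentrated at the
dendrite base; at the tip and at smaller steps agreement is considerably
better. The electrical step response completes (stays within 5% of steady)
in just under 9 ms at the tip, with half-rise and half-fall times of square
pulses between 0.5 and 2.5 ms across the physiological conductance range
6.4×10⁻²–4 nS — confirming that the slow experimental SP kinetics (hundreds
of ms to tens of s) cannot originate in the electrical circuit.

## Parameters

The bundled YAML files carry the *Antheraea polyphemus* parameterization:
geometry and passive electrics (dendrite length 220 µm, diameter 0.475 µm,
membrane resistivity 7500 Ω·cm², lymph/axoplasm resistivity 40 Ω·cm, soma
area 144 µm², batteries `E_ls = −62` mV, `E_a = −35` mV, 1 µF/cm²) and the
channel constants (reversal potentials, whole-dendrite maximal
conductances, agonist EC50s and Hill coefficients, antagonist IC50s and
maximal inhibitions, charge-to-concentration factors). `derive_cable_params()`
computes the full derived chain — space constant λ ≈ 455 µm, time constant
τ = 7.5 ms, electrotonic length `l_d ≈ 0.484`, load ratios — and
`scale_to_compartments()` distributes whole-dendrite quantities over `N`
compartments (membrane quantities divided by `N`, series conductances
multiplied by `N`, so re-aggregation is exact).

Two derived entries deserve a note. The published table prints
`r_in = 0.900` and `a = 0.3018`; its own formulas
(`(R_ls + R_a)/(λ(r_e + r_i))` and `R_a/(R_ls + R_a)` with
`R_a = R_api + R_bas = 325 MΩ`) give 0.923 and 0.319. Both printed values
are recovered exactly if `R_a` is taken as the apical resistance alone
(300 MΩ), suggesting the basolateral term was dropped in the published
ratios. This package derives faithfully from the stated formulas and uses
the result consistently in both the circuit and the analytics, so every
numeric-vs-analytic comparison is internally coherent; only the comparison
against the printed 0.900 itself disagrees. Similarly the printed
whole-dendrite volume (38 µm³) and leak conductance (0.4373 nS) differ from
their own formulas by under 1%; tests compare those entries at 1%.

Internal units are mV, nS, pA, pF and µM with time in seconds (capacitances
are converted to nF inside the right-hand sides so that pA/nF = mV/s);
derived quantities keep their conventional reporting units (λ in µm, τ in
ms).

## The synthetic transduction drive

The upstream biochemistry — receptor activation, G-protein/effector
kinetics, second-messenger synthesis — is *not* re-derived here; those
equations are not part of this model's printed description. Instead
`drive_protocol()` supplies deterministic waveforms through a pluggable
interface (time, uptake → messenger concentrations), so a full cascade can
be substituted later (including tabulated time series via the
`external` kind):

* IP₃ and DAG follow a biphasic waveform (default): a fast transient surge
  (rise 50 ms, decay 0.4 s — producing the transient cationic current) on
  top of a sustained component (time constant 1.5 s), all scaled by a
  saturating dose factor `U/(K_U + U)` with `K_U = 0.2` µM/s;
* intradendritic Ca²⁺ integrates the Ca-carrying currents: influx through
  the Ca²⁺ and cationic channels (factors `f_Ca`, `f_cat`), extrusion by
  NCX (factor `F`). The NCX term enters with the sign opposite to its
  charge flux (3 Na⁺ in per Ca²⁺ out), so the forward, inward-current mode
  removes Ca²⁺. Conversion factors are calibrated per whole-dendrite
  volume, so per-compartment rates scale with `N`;
* CaCaM, PKC\* and somatic Ca²⁺ are low-pass-filtered copies of Ca²⁺ (time
  constants 0.5 s, 1 s, 0.3 s; gains 0.02, 0.005, 0.01), preserving the
  feedback ordering of the cascade.

The waveform amplitudes (`IP3_max = 10` µM against an EC50 of 3.48 µM,
`DAG_max = 0.1` µM against 0.0104 µM) were chosen once so that the standard
dose grid (26 uptakes, 10⁻⁴·⁷⁵–10¹·⁵ µM/s) spans the response range:
RP at the soma grows sigmoidally from ≈0.4 mV to ≈28 mV ("about 30 mV"),
SP mirrors it with opposite sign, intradendritic Ca²⁺ stays below 200 µM,
the cationic conductance is transient and the Cl⁻ conductance sustained and
biphasic (bump then wave). What the generator does **not** emulate: the
quantitative EC50 cascade of the real upstream reactions (receptor,
effector), perireceptor transport and deactivation kinetics, and hence the
absolute sensitivity (the published ≈170-fold cascade amplification).
Passing tests demonstrate the electrical organ model and the
characterization machinery, not the upstream biochemistry.

## Response characterization and fitting

`characterize()` reduces a kinetic curve to the three standard summary
numbers: signed extremum height, half-rise time (stimulus onset → first
crossing of half the height) and half-fall time (stimulus offset → first
half-height crossing after the extremum; negative when the response decays
below half-maximum before the stimulus ends, as the transient cationic
conductance does). Crossings are linearly interpolated; the first-crossing
rule reproduces the non-monotonic rise-time behavior of biphasic curves
(bump-determined at low drive, wave-determined at high drive).
`ec50()` interpolates the half-maximal dose in log-dose space;
`amplification_ratios()` computes the relative conductance-to-voltage gain
`f_r = H_r/G_r`, ≈8.5 at 0.01 nS with the standard parameters, declining to
1 at 10 nS.

`fit_cost()` implements the weighted characteristics cost
`J(θ) = Σ_i w_H|ΔH_i| + w_rise|Δτ_rise,i| + w_fall|Δτ_fall,i|`. The
published description does not print the weights; the defaults
(`w_H = 1` per mV, `w_rise = w_fall = 10` per second) are this package's
choice, weighting 0.1 s of kinetic error like 1 mV of amplitude error, and
are exposed in `fit_target()`. Missing characteristics draw a fixed
per-miss penalty (10 × weight); model failures a large finite penalty.
`optimize_fit()` wraps Nelder–Mead (`stats::optim`), unconstrained as in
the original estimation procedure, with bounds enforced by a quadratic
penalty and optional seeded restarts. `recovery_experiment()` demonstrates
closure: dose-response targets generated at the bundled `G_Mcat`, `G_MCl`,
`G_MK`, starts perturbed by ±20%, recovery to well within 5% (typically
<1%), with the qualitative screens (transient cationic current, sustained
Cl⁻ current, Ca²⁺ < 200 µM) reported alongside.

## Numerical choices and problem sizes

* Steady states are obtained either by direct sparse nodal solve
  (`steady_state_simplified()`, exact) or by integrating to 0.2 s ≈ 27
  membrane time constants; the two agree to the solver tolerance.
* The lumped-conductance division guards a driving-force floor of 10⁻⁶ mV;
  flagged samples are interpolated from temporal neighbours.
* The cosine series truncates when a term's amplitude falls below 10⁻¹⁰ mV
  (hard cap 10⁴ terms).
* Test and validation problem sizes were chosen to keep the default suite
  fast while exercising every claim: the fine-grid cable oracle uses
  `N = 2000`; replay equivalence uses `N = 6` at three doses with a 125-µs
  conductance table (the replay error is interpolation-limited and falls
  below 2×10⁻⁴ of the response scale); parameter recovery uses `N = 2`,
  three doses and ≈200 cost evaluations (the experiment checks optimizer
  closure, not spatial convergence — the equivalence and convergence
  properties are established separately and are N-independent).

## Known limitations

* Action potentials are outside the model; the soma is purely passive plus
  the K⁺ branch.
* Single-ORN sensilla only; paired-ORN interactions are not represented.
* The synthetic drive is a stand-in: quantitative dose-response positions
  (EC50s in uptake) reflect its dose-scaling rule, not the real cascade.
* The small-signal transient solution inherits ≈20% worst-case error at
  the upper end of its validity range; it is an approximation for insight
  and validation, not a replacement for integration.
* All conductances are deterministic ensemble means; single-channel noise
  is not modelled.
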