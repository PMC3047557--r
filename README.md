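# sensillum

Electrical-circuit modelling of the moth pheromone-sensitive sensillum: the
receptor potential (RP) of the olfactory receptor neuron (ORN) and the
tip-recorded sensillar potential (SP), simulated from the interplay of
pheromone-gated ionic currents, the long outer dendrite, and the
auxiliary-cell epithelium.

## The scientific problem

A moth pheromone sensillum is a hair-like organ: the ORN's sensory outer
dendrite (length *L*<sub>d</sub> ≈ 220 µm) is bathed in sensillar lymph,
separated from the hemolymph by auxiliary cells whose battery generates a
transepithelial potential. Pheromone-gated channels in the dendritic
membrane depolarize the neuron (RP) and, through the lymph return path,
pull the recorded hair-tip potential negative (SP). Whether the measured SP
kinetics reflect transduction chemistry or the electrical anatomy of the
organ — and how many compartments a model dendrite needs — are quantitative
questions this package addresses.

The package provides, for users who model sensory transduction or analyze
sensillar recordings:

* a **complete multicompartment model**: the dendrite split into *N*
  isopotential compartments (default 40), each with leak and four
  Hill-gated, pheromone-dependent currents — IP₃-gated Ca²⁺, DAG-gated
  cationic, Ca²⁺-gated Cl⁻, and Na⁺/Ca²⁺ exchange — with CaCaM/PKC\*
  feedback inhibition raising the EC50s
  (`g = g_max·Yⁿ/(K_yⁿ + Yⁿ)`, `K_y = K_my·(1 + (i_My−1)·Zⁿⁱ/(K_iyⁿⁱ + Zⁿⁱ))`),
  a Ca²⁺ mass balance per compartment, and a Ca²⁺/voltage-gated K⁺ current
  at the soma;
* a **simplified single-conductance model**: one lumped branch
  `g_p_j(t)·(V − E_p)` per compartment with `E_p = 0`, exactly equivalent to
  the complete model when driven by the replayed lumped conductance;
* **closed-form steady-state cable solutions** (hyperbolic profile
  `W(x) = W_∞ + A·cosh(qx)`, `q = √(1+g)`, sealed tip, lumped soma +
  auxiliary load) and a **small-signal cosine-series transient**, used as
  analytic oracles for the numerics;
* **dose-response characterization** (height, half-rise, half-fall, EC50,
  amplification ratios) and **Nelder–Mead fitting** of response
  characteristics with parameter-recovery validation.

Parameters ship as editable YAML (the *Antheraea polyphemus*
parameterization: λ ≈ 455 µm, τ = 7.5 ms, electrotonic length ≈ 0.48).

## Worked example

```r
library(sensillum)

base <- sensillum_base_params()            # Table of basic geometry/electrics
d    <- derive_cable_params(base)          # derived cable chain
d
#> Derived sensillum cable parameters:
#>   S_d = 328.3 um^2, C_d = 3.283 pF, G_ld = 0.4377 nS
#>   lambda = 455.1 um, tau = 7.50 ms, l_d = 0.4834
#>   E_ld = -97.0 mV, r_in = 0.9232, a = 0.3188
#>   G_e = 26.90 nS, G_i = 2.014 nS, G_ls = 1.440 nS, G_a = 3.077 nS

sc <- scale_to_compartments(d, channel_params(), N = 40)

# steady state of the simplified model at 1 nS total conductance,
# against the closed-form cable solution
st <- steady_state_simplified(sc, G_p = 1)
c(RP_b = attr(st, "RP_b"), RP_s = attr(st, "RP_s"), SP = attr(st, "SP"))
#>      RP_b      RP_s        SP
#>  36.84     24.77    -12.23          # mV, numerical N = 40
c(steady_rp_base(d, 1), steady_rp_soma(d, 1), steady_sp(d, 1))
#> 36.50  24.86 -12.26                 # mV, analytic

# complete model: 2-s pheromone pulse at uptake 0.1 uM/s
tr <- integrate_complete(sc, drive_protocol(), U = 0.1, t_end = 15,
                         dt_out = 0.02,
                         solver = list(method = "lsoda", rtol = 1e-6,
                                       atol = 1e-9, hmax = 0.05))
characterize(tr$time, tr$SP, onset = 0, offset = 2)
#> $height    -23.4      # mV: SP swings negative, mirroring RP
#> $tau_rise    0.13     # s: half-rise, set by the transduction kinetics
#> $tau_fall   10.0      # s: slow return, set by Ca2+ clearance
```

The numbers tell the story: the dendrite is electrically compact (the
analytic and `N = 40` numerical steady states agree to <1%), SP is a fixed
fraction of RP at all stimulus strengths, and the organ's electrical
response is complete within milliseconds — the tens-of-seconds SP decay can
only come from the transduction chemistry, not the circuit.

A thin command-line wrapper exposes the same functionality
(`exec/sensillum derive-params|simulate|dose-response|analytic-compare|sweep|fit`),
writing delimited tables plus a YAML run manifest.

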