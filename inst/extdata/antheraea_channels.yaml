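# Second-messenger and ionic-current parameters of the Antheraea sensillum
# model. Maximal conductances G_M are whole-outer-dendrite totals (nS); for N
# compartments the per-compartment value is G_M/N. Potentials mV,
# concentrations uM, Hill coefficients and maximal inhibitions dimensionless,
# conversion factors uM/pC.
s_M: 653              # maximal second-messenger synthesis rate (1/s)
Ca:                   # IP3-gated Ca2+ current, inhibited by CaCaM
  E: 140
  G_M: 0.137
  K_m: 3.48
  "n": 1
  i_M: 3.08
  K_i: 0.61
  n_i: 2.51
  agonist: IP3
  antagonist: CaCaM
cat:                  # DAG-gated cationic current, inhibited by CaCaM
  E: 0
  G_M: 0.877
  K_m: 0.0104
  "n": 0.776
  i_M: 53.2
  K_i: 0.0377
  n_i: 0.818
  agonist: DAG
  antagonist: CaCaM
Cl:                   # Ca2+-gated chloride current, inhibited by PKC*
  E: -11.5
  G_M: 12.1
  K_m: 81.2
  "n": 1.443
  i_M: 1.4
  K_i: 0.06
  n_i: 1.1
  agonist: Ca
  antagonist: PKCstar
x:                    # Na+/Ca2+ exchanger (NCX), Ca2+-dependent, no antagonist
  E: -25.7
  G_M: 2.21e-3
  K_m: 0.54
  "n": 0.605
  agonist: Ca
K:                    # Ca2+- and voltage-gated K+ current (inner dendrite/soma)
  E: -62
  G_M: 1.6091
  K_m: 2.803e-4
  A_K: 12.5
F: 136.37             # charge-to-concentration conversion, NCX (uM/pC)
f_Ca: 4.87            # idem, IP3-gated channels (uM/pC)
f_cat: 2.50           # idem, DAG-gated channels (uM/pC)
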