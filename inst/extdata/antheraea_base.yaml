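# Basic geometrical and passive electrical parameters of the Antheraea
# polyphemus pheromone-sensitive sensillum (trichodeum, cell A, cut-hair
# tip-recording conditions). Keys are the field's standard symbols.
# Units: lengths/diameters um, areas um^2, membrane resistivities Ohm.cm^2,
# medium resistivities Ohm.cm, potentials mV, capacitances pF, resistances
# MOhm, specific capacitance uF/cm^2.
L_d: 220        # outer dendrite length (um)
D_i: 0.475      # outer dendrite mean diameter (um)
rho_ld: 7500    # outer dendrite membrane resistivity (Ohm.cm^2)
D_e: 1.8        # hair-lumen mean inside diameter (um)
rho_e: 40       # sensillar lymph resistivity (Ohm.cm)
rho_i: 40       # intracellular resistivity (Ohm.cm)
S_s: 144        # inner dendrite + soma lateral area (um^2)
rho_ls: 1000    # inner dendrite + soma membrane resistivity (Ohm.cm^2)
E_ls: -62       # soma leak equilibrium potential (mV)
C_api: 30       # auxiliary-cell apical membrane capacitance (pF)
R_api: 300      # auxiliary-cell apical membrane resistance (MOhm)
rho_bas: 100    # auxiliary-cell basolateral membrane resistivity (Ohm.cm^2)
R_bas: 25       # auxiliary-cell basolateral membrane resistance (MOhm)
E_a: -35        # auxiliary battery, source of the transepithelial potential (mV)
c: 1            # specific membrane capacitance, all membranes (uF/cm^2)
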