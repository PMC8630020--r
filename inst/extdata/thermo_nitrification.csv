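# Standard-state formation properties at 25 C, 1 bar.
# dGf/dHf in kJ/mol from standard geochemical compilations
# (CODATA/Wagman-family values as used in aqueous-speciation references);
# H+ is zero by convention. Ion-size parameters in Angstrom (Kielland).
species,dGf_kJ_mol,dHf_kJ_mol,charge,ion_size_A
NH3,-26.50,-80.29,0,0
NH4,-79.31,-132.51,1,2.5
O2,16.44,-11.70,0,0
NO3,-111.30,-207.30,-1,3.0
H,0,0,1,9.0
H2O,-237.18,-285.83,0,0
Mn,-228.10,-220.75,2,6.0
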