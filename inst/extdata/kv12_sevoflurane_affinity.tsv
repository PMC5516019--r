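# Restrained-FEP inputs for sevoflurane binding to the open Kv1.2 pore
# domain: per-site harmonic restraint constants (kcal/mol/A^2), cumulative
# reversible work values W*_n (kcal/mol, gas phase -> n bound) and their
# statistical errors. Level-2 work values are two-step compositions
# W*_2 = W*_1 + W*_2|1; the extracellular-face sites support single
# occupancy only.
site_id	region	level	k_list	work_kcal_mol	error_kcal_mol
S01	S6P-helix	1	0.053	-4.5	0.2
S01	S6P-helix	2	0.196	-8.1	0.4
S02	S6P-helix	1	0.141	-4.7	0.2
S02	S6P-helix	2	0.137	-9.0	0.4
S03	S6P-helix	1	0.084	-5.0	0.2
S03	S6P-helix	2	0.084	-8.8	0.5
S04	S6P-helix	1	0.036	-3.8	0.3
S04	S6P-helix	2	0.174	-7.1	0.7
S05	ext-face	1	0.530	1.5	0.4
S06	ext-face	1	0.453	-0.8	0.4
S07	ext-face	1	0.283	-0.8	0.4
S08	ext-face	1	0.332	-4.2	0.5
S09	S4S5-linker	1	0.061	-6.4	0.2
S09	S4S5-linker	2	0.004	-10.4	0.5
S10	S4S5-linker	1	0.127	-7.5	0.0
S10	S4S5-linker	2	0.004	-12.7	0.2
S11	S4S5-linker	1	0.037	-6.7	0.3
S11	S4S5-linker	2	0.003	-13.7	0.6
S12	S4S5-linker	1	0.058	-5.6	0.3
S12	S4S5-linker	2	0.003	-11.7	0.6
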