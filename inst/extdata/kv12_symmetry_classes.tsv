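# Symmetry classes of the homotetrameric Kv1.2 channel: the twelve resolved
# sevoflurane sites reduce to three distinguishable regions under the 4-fold
# axis.
class_id	site_id
S6P-helix	S01
S6P-helix	S02
S6P-helix	S03
S6P-helix	S04
ext-face	S05
ext-face	S06
ext-face	S07
ext-face	S08
S4S5-linker	S09
S4S5-linker	S10
S4S5-linker	S11
S4S5-linker	S12
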