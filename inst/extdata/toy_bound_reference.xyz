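# bound reference pose of the toy association model (length units)
rec_centre 0 0 0
rec_patch 0 0 12
rec_eq1 12 0 0
rec_eq2 0 12 0
lig_centre 0 0 20
anchor1 0 0 12
anchor2 0 0 28
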