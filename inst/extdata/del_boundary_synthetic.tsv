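#backbone=chr2:182113224
del_boundary_bins_synthetic	deletion	chr2	74400000	74760000	0	.
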