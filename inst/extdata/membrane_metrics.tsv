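membrane	metric	value	sd	unit
Ld	area_per_lipid	0.651	0.002	nm^2
Ld	thickness	3.90	0.01	nm
Ld	d_xy	1.20e-7	0.24e-7	cm^2/s
Ld	k_a	1.08839	NA	N/m
Lo	k_a	3.48643	NA	N/m
Lo	d_xy	1.2e-8	NA	cm^2/s
Lo	collapse_pressure	53.0	NA	mN/m
Lo	limiting_area	43.1	NA	A^2/molecule
Ld	collapse_pressure	40.6	NA	mN/m
Ld	limiting_area	84.8	NA	A^2/molecule
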