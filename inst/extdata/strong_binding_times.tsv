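membrane	lipid	compound	mean	sd
Ld	POPC	EC	109.2	17.2
Ld	POPC	ECG_dimer	236.0	9.1
Ld	POPC	EGCG_dimer	208.2	41.1
Lo	PSM	EC	12.8	10.4
Lo	PSM	ECG_dimer	184.7	23.3
Lo	PSM	EGCG_dimer	129.9	44.3
Lo	CHOL	EC	1.6	0.4
Lo	CHOL	ECG_dimer	1.5	1.0
Lo	CHOL	EGCG_dimer	10.6	12.8
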