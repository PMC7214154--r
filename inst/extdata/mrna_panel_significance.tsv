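# qPCR panel of 36 left-ventricular transcripts, 7 d post-infarction:
# significance (P <= .05) of each conditioning arm vs the I/R group,
# transcribed from the published fold-change table of the rat
# post-conditioning study the synthetic generators emulate.
feature_id	sig_ipocr	sig_ipocnr	sig_ipc
Arrb2	TRUE	TRUE	TRUE
Foxn3	TRUE	TRUE	TRUE
Zbtb20	TRUE	TRUE	TRUE
Efhd2	TRUE	TRUE	FALSE
Grk2	TRUE	TRUE	FALSE
Vegfa	TRUE	TRUE	FALSE
Col3a1	TRUE	FALSE	TRUE
Eln	TRUE	FALSE	TRUE
Psme3	TRUE	FALSE	TRUE
Arg1	TRUE	FALSE	TRUE
Casr	TRUE	FALSE	TRUE
Bcl2	TRUE	FALSE	TRUE
Adm2	TRUE	FALSE	TRUE
Bgn	TRUE	FALSE	FALSE
Col1a1	TRUE	FALSE	FALSE
Cybb	TRUE	FALSE	FALSE
Fn1	TRUE	FALSE	FALSE
Jdp2	TRUE	FALSE	FALSE
Tgfb1	TRUE	FALSE	FALSE
Ramp1	TRUE	FALSE	FALSE
Pthlh	TRUE	FALSE	FALSE
Ramp3	TRUE	FALSE	FALSE
Nos2	TRUE	FALSE	FALSE
Arg2	TRUE	FALSE	FALSE
Arrb1	TRUE	FALSE	FALSE
Nos3	TRUE	FALSE	FALSE
Ramp2	TRUE	FALSE	FALSE
Grk5	TRUE	FALSE	FALSE
Mdm2	TRUE	FALSE	FALSE
Cxcl12	TRUE	FALSE	FALSE
Oxsr1	TRUE	FALSE	FALSE
Ppargc1b	TRUE	FALSE	FALSE
Atp2a2	TRUE	FALSE	FALSE
Adrb2	TRUE	FALSE	FALSE
Pln	FALSE	FALSE	FALSE
Socs7	TRUE	FALSE	FALSE
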