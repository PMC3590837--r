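segment,mass_fraction,com_fraction,length_fraction,rg_sagittal,rg_transverse,rg_longitudinal,source
humerus,0.0271,0.5772,0.186,0.285,0.269,0.158,de Leva 1996 adjusted Zatsiorsky (male); length fraction Drillis-Contini
forearm,0.0162,0.4574,0.146,0.276,0.265,0.121,de Leva 1996 adjusted Zatsiorsky (male); length fraction Drillis-Contini
hand,0.0061,0.7900,0.108,0.628,0.513,0.401,de Leva 1996 adjusted Zatsiorsky (male); length fraction Drillis-Contini
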