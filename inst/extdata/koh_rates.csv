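species,k_oh,note
isoprene,1.0e-10,IUPAC-recommended room-temperature value
alpha-pinene,5.3e-11,IUPAC-recommended room-temperature value
beta-pinene,7.9e-11,IUPAC-recommended room-temperature value
limonene,1.7e-10,IUPAC-recommended room-temperature value
methanol,9.4e-13,IUPAC-recommended room-temperature value
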