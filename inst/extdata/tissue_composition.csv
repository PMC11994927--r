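# Fractional tissue composition for tissue-to-plasma partitioning of neutral
# compounds: extracellular water, intracellular water, neutral lipid, neutral
# phospholipid, and the tissue-to-plasma albumin ratio. Transcribed (rounded)
# from the published human composition tables used by the Rodgers-Rowland
# partitioning method. "rest" is a generic lean-tissue surrogate.
tissue,f_ew,f_iw,f_nl,f_np,albumin_ratio
adipose,0.135,0.017,0.853,0.0016,0.049
brain,0.162,0.620,0.0391,0.0015,0.048
gut,0.282,0.475,0.0487,0.0163,0.158
heart,0.320,0.456,0.0115,0.0166,0.157
kidney,0.273,0.483,0.0207,0.0162,0.130
liver,0.161,0.573,0.0348,0.0252,0.086
lung,0.336,0.446,0.0022,0.0128,0.212
muscle,0.118,0.630,0.0238,0.0072,0.064
skin,0.382,0.291,0.0284,0.0111,0.277
rest,0.300,0.450,0.0400,0.0100,0.100
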