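# Reference adult human physiology (70 kg, 30-y European) used by the PBPK model.
# Organ volumes and regional blood flows transcribed from standard published
# human-physiology compilations (ICRP-style reference values, rounded).
# flow_l_h for liver is the hepatic-arterial flow; portal inflow is the gut flow.
compartment,volume_l,flow_l_h
blood,5.2,NA
gut,1.1,46.8
liver,1.8,25.8
kidney,0.31,74.4
muscle,29,45
adipose,13.5,15.6
skin,3.3,18
brain,1.45,42
heart,0.33,14.4
lung,0.53,15
rest,8,39
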