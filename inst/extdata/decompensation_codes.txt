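# Decompensating complications: ascites, encephalopathy, varices,
# hepatorenal syndrome, SBP
R18*
789.5*
K72.9*
K72.1*
572.2
I85*
456.0
456.1
456.2*
K76.7
572.4
K65.2
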