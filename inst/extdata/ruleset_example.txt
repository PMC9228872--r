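# Example feature rule-set override: listed types replace the built-in
# perception for that type; positions are matched-atom-set centroids.
# One "<TYPE> <SMARTS>" per line.
A [OX1]=C
A [nX2]
D [OX2H]
D [NH]
D [NH2]
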