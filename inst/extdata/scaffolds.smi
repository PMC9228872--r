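OC(=O)CCCCN1C(=O)Nc2ccccc2C1=O 2a
OC(=O)CCCCCN1C(=O)Nc2ccccc2C1=O 2b
OC(=O)CCCCCCN1C(=O)Nc2ccccc2C1=O 2c
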