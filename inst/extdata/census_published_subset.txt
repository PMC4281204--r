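CBFA2T3
EBF1
FHIT
MYC
PTEN
RANBP17
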