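# Targeted-therapy drug names (one per line); defines the TT-Yes label.
trastuzumab
pertuzumab
lapatinib
neratinib
palbociclib
ribociclib
abemaciclib
everolimus
olaparib
alpelisib
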