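# Additional maskable (non-targeted) drug names; the masking set is the
# union of this list with the targeted list.
tamoxifen
letrozole
anastrozole
exemestane
fulvestrant
capecitabine
paclitaxel
doxorubicin
cyclophosphamide
carboplatin
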