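>hTelo
GGGTTAGGGTTAGGGTTAGGG
>cKIT1
GGGAGGGCGCTGGGAGGAGGGA
>cKIT1_fret
AGGGAGGGCGCTGGGAGGAGGGGC
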