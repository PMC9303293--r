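>extension_primer_cy5
CTAGAGCTAGAGTGCTCGGC
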