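>KIT_LNA1
CCC+T+C+C+TCCCAGCGCCCTCCC
>KIT_LNA2
T+C+C+C+TCCTCCCAGCGCCCTCCC
>KIT_LNA3
TC+CCTCCTC+CCAGCGC+CCTC+CC
>KIT_LNA4
TCCC+TC+CTCCC+AG+CGCCCTCCC
>KIT_DNA1
TCCCTCCTCCCAGCGCCCTCCC
>hTelo_LNA1
+C+C+C+TAACCCTAACCCTAACCC
>hTelo_LNA2
CCC+TAACC+CTA+ACCCT+AACCC
>hTelo_DNA1
CCCTAACCCTAACCCTAACCC
>KIT_LNA_short
T+C+C+C+TCCTCC
>KIT_DNA_short
TCCCTCCTCC
>hTelo_LNA_short
+C+C+C+TAACCCT
>hTelo_LNA_short2
C+CC+TAA+CCC+T
>hTelo_DNA_short
CCCTAACCCT
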