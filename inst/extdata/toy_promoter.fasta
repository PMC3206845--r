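>TOY_PROMOTER:1-541 synthetic toy promoter with 30 CpG sites
GATTACATTACCATGGATCACTCGTTACCATGGATCACTCGTTACCATGGATCACTCGTTACCATGGATC
ACTCGTTACCATGGATCACTCGTTACCATGGATCACTCGTTACCATGGATCACTCGTTACCATGGATCAC
TCGTTACCATGGATCACTCGTTACCATGGATCACTCGTTACCATGGATCACTCGTTACCATGGATCACTC
GTTACCATGGATCACTCGTTACCATGGATCACTCGTTACCATGGATCACTCGTTACCATGGATCACTCGT
TACCATGGATCACTCGTTACCATGGATCACTCGTTACCATGGATCACTCGTTACCATGGATCACTCGAAA
AAAAAAAAAAAAATTACCATGGATCACTCGTTACCATGGATCACTCGTTACCATGGATCACTCGTTACCA
TGGATCACTCGTTACCATGGATCACTCGTTACCATGGATCACTCGTTACCATGGATCACTCGTTACCATG
GATCACTCGTTACCATGGATCACTCGTTACCATGGATCACTCGTGATTACA
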