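>RNSB-C_seed1
LSEDEAWELFKN
>RNSB-C_seed2
LSEDEAWELFKN
>RNSB-C_seed3
LGEDDAWELWKN
>RNSB-C_seed4
LGEDEAWELWKN
>RNSB-C_seed5
LAEDEAWELFKN
>RNSB-C_seed6
LSEDEAWELFHN
>RNSB-C_seed7
LSDDEAWELFKN
>RNSB-C_seed8
LSEEEAWELWHN
>RNSB-C_seed9
LSEDDAWELFHN
>RNSB-C_seed10
LAEDEAWELFRN
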