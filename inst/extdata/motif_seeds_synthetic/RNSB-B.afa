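>RNSB-B_seed1
NGSRIIITTRNE
>RNSB-B_seed2
NSSRIIITTRNE
>RNSB-B_seed3
NGGRIIITTRND
>RNSB-B_seed4
NASHIIITTRND
>RNSB-B_seed5
NGSKIIITTRNE
>RNSB-B_seed6
NGSRIIITTRNE
>RNSB-B_seed7
QGSKIIITTRTE
>RNSB-B_seed8
NGSRIIITTRNE
>RNSB-B_seed9
NGARIIITTRTE
>RNSB-B_seed10
NSSHIIITTRSE
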