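>RNSB-D_seed1
CFLYCALFPEDY
>RNSB-D_seed2
CFLYCGLFPEDY
>RNSB-D_seed3
CFLYCAMFPEDF
>RNSB-D_seed4
CFLYCAIFPDDY
>RNSB-D_seed5
CFLYCALFPEDY
>RNSB-D_seed6
CFLYCSMFPDEF
>RNSB-D_seed7
CFLYCSLFPEDY
>RNSB-D_seed8
CFLYCALFPEDY
>RNSB-D_seed9
CFLYCALFPEDY
>RNSB-D_seed10
CFLYCALFPEDY
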