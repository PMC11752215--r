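>RNSB-A_seed1
FDLKAWVCVSQN
>RNSB-A_seed2
FEIKAWVCLSQT
>RNSB-A_seed3
FEVKAWVCVSQN
>RNSB-A_seed4
FDLKAWVCMGQQ
>RNSB-A_seed5
FELKAWVCVGQN
>RNSB-A_seed6
FDIKAWVCLSQN
>RNSB-A_seed7
FDMKAWVCVSQN
>RNSB-A_seed8
FDLKAWVCIGQT
>RNSB-A_seed9
FDVKAWVCLSQN
>RNSB-A_seed10
FELKAWVCVSTN
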