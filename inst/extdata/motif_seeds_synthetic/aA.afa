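>aA_seed1
AKLLKAIEESRI
>aA_seed2
SKLLKAIEESRI
>aA_seed3
AKLLKAIEESRV
>aA_seed4
AKLLKAIEDSRL
>aA_seed5
GKLLKAIEESRM
>aA_seed6
AKLVHAIEDSHI
>aA_seed7
AKLLKAIDESRI
>aA_seed8
AKLIKAIEEAHI
>aA_seed9
AKLMKAIEESRI
>aA_seed10
AKLIRAIEEGRV
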