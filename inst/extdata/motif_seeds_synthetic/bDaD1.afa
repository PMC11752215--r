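>bDaD1_seed1
GIVVFSENYASS
>bDaD1_seed2
GIVVFSENFASS
>bDaD1_seed3
AIVVFSESFASS
>bDaD1_seed4
GIVVFSENYASG
>bDaD1_seed5
GIVVFSENYASA
>bDaD1_seed6
SIVVFSETYAGS
>bDaD1_seed7
GIVVFSENYASS
>bDaD1_seed8
AIVVFSENYAGS
>bDaD1_seed9
GLVVFSENYASS
>bDaD1_seed10
GIVVFSENYSSG
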