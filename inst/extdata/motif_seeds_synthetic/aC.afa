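>aC_seed1
EEVERWRKALTE
>aC_seed2
EEVERWRKAMTE
>aC_seed3
EEVDRWRKAITE
>aC_seed4
EELERWRKALSD
>aC_seed5
EDMDRWRKALTE
>aC_seed6
EDVERWRKAMTE
>aC_seed7
EEVERWRKALTE
>aC_seed8
EDVERWRKALTE
>aC_seed9
EEVERWRKALTE
>aC_seed10
EDVERWRKGMTE
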