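>MHD_seed1
CKMHDVVREMAL
>MHD_seed2
CKMHDIVREMSL
>MHD_seed3
CKMHDMVREMAL
>MHD_seed4
CKMHDVVREMAL
>MHD_seed5
CHMHDVLHEMSI
>MHD_seed6
CKMHDMVREMSL
>MHD_seed7
CKMHDVVREIAV
>MHD_seed8
CKMHDVVREMAL
>MHD_seed9
CHMHDVVHEMAL
>MHD_seed10
CKMHDMVREMGV
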