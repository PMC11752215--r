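>aD3_seed1
WREALNEVANLS
>aD3_seed2
WREALQEVANLA
>aD3_seed3
WHDALNDVANLA
>aD3_seed4
WKEALNEIANIA
>aD3_seed5
WREALNEISNLS
>aD3_seed6
WKEALNEIANLS
>aD3_seed7
WREALTEVASLG
>aD3_seed8
WHEALNEVSSLS
>aD3_seed9
WREALNEVSNVG
>aD3_seed10
WKEALSEVANLS
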