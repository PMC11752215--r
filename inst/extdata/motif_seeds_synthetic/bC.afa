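>bC_seed1
VLPIFYDVDPSD
>bC_seed2
LVPIFYDVDPSE
>bC_seed3
VVPIFYDVDPAD
>bC_seed4
VLPIFYDVDPSD
>bC_seed5
VLPIFYDIDPSE
>bC_seed6
VLPIFYDVDPSD
>bC_seed7
VLPIFYDVDPGD
>bC_seed8
VVPIFYDVDPSD
>bC_seed9
VIPIFYDLDPSD
>bC_seed10
VLPIFYDVDPSD
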