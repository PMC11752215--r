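>VG_seed1
VGLEDELDKLLE
>VG_seed2
VGLEDELDKLLE
>VG_seed3
VGVEDEIDRLLE
>VG_seed4
VGLEDEVERLLE
>VG_seed5
VGLEEELDKLMD
>VG_seed6
VGLEDELDKLLE
>VG_seed7
VGLEEELDKLME
>VG_seed8
VGVEDDLDKLLE
>VG_seed9
VGIDDELDKVVE
>VG_seed10
VGLEEELEKMLE
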