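>GLPL_seed1
AGLPLALITLGS
>GLPL_seed2
AGLPLALVSMGS
>GLPL_seed3
AGLPLAIITLAS
>GLPL_seed4
AGLPLALITLGS
>GLPL_seed5
AGLPLAIIQLGS
>GLPL_seed6
AGLPLALITLGS
>GLPL_seed7
AGLPLAVMTLGS
>GLPL_seed8
AGLPLALIQLAS
>GLPL_seed9
AGLPLAVLTLGS
>GLPL_seed10
AGLPLALITMGG
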