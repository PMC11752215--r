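>P-loop_seed1
GMGGVGKTTLAQ
>P-loop_seed2
GMGGVGKTTLAQ
>P-loop_seed3
GMGGVGKTTMAQ
>P-loop_seed4
GMGGVGKTTIAQ
>P-loop_seed5
GMGGVGKTTLSQ
>P-loop_seed6
GMGGVGKTSLAT
>P-loop_seed7
GMGGVGKTTLAS
>P-loop_seed8
GMGGVGKTTLAQ
>P-loop_seed9
GMGGVGKTQLGQ
>P-loop_seed10
GMGGVGKTTLGS
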