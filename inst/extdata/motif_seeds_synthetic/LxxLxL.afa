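>LxxLxL_seed1
LRELDLSGNKLS
>LxxLxL_seed2
LRELELAGSHLS
>LxxLxL_seed3
LKELDLAGNRMS
>LxxLxL_seed4
LRELDLSGNKLS
>LxxLxL_seed5
LRDLDLSGNKLS
>LxxLxL_seed6
LRELDLSGSKLS
>LxxLxL_seed7
LRDLDLSGQRLS
>LxxLxL_seed8
LRELDLAGNKLS
>LxxLxL_seed9
LRELELSGQKLA
>LxxLxL_seed10
LHELDLSGNKLS
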