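>extended-EDVID_seed1
RAEELEDVIDGL
>extended-EDVID_seed2
RAEELEDVIDSV
>extended-EDVID_seed3
KADELEDVIDGL
>extended-EDVID_seed4
KAEELEDVIDGL
>extended-EDVID_seed5
RADELEDVIDGV
>extended-EDVID_seed6
RADELEDVIDAM
>extended-EDVID_seed7
KAEELEDVIEGL
>extended-EDVID_seed8
RAEELEDVIESL
>extended-EDVID_seed9
RGDELEDVIDGL
>extended-EDVID_seed10
RAEDLEDVIDGL
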