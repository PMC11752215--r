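>Walker-B_seed1
KYLIVLDDVWDT
>Walker-B_seed2
HYLIVLDDVWET
>Walker-B_seed3
RYLIVLDDVWET
>Walker-B_seed4
RFMIVLDDVWDN
>Walker-B_seed5
KYLIVLDDVWDS
>Walker-B_seed6
KYVIVLDDVFET
>Walker-B_seed7
RYLIVLDDVWDT
>Walker-B_seed8
KYLIVLDDVWDT
>Walker-B_seed9
KYLIVLDDVWDN
>Walker-B_seed10
KYLIVLDDVWDN
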