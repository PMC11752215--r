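>bA_seed1
YDVFLSFRGEDT
>bA_seed2
YDVFLSFRGEDT
>bA_seed3
YDIFLSFRGEDT
>bA_seed4
WDVFLSFRGEDT
>bA_seed5
WDMFLSFRADDN
>bA_seed6
FEVFLSFRAEDS
>bA_seed7
YDMFLSFRGEDT
>bA_seed8
YEVFLSFRGEDN
>bA_seed9
YDVFLSFRGDDQ
>bA_seed10
YDIFLSFRGEDS
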