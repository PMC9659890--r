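n_co_aps,n_patients
0,9073
1,2691
2,1067
3,477
4,233
5,116
6,142
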