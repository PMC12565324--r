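pair,n
1-1,11
1-2,10
1-3,2
2-2,33
2-3,8
3-3,9
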