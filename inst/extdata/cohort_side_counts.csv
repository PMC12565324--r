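cluster,right,left
1,17,17
2,44,45
3,12,16
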