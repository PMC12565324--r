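cluster,female,male
1,15,19
2,47,41
3,19,8
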