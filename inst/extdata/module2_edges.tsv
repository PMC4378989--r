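from	to
met7	met8
met8	met9
met8	met10
met9	met11
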