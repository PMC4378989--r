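from	to
met1	met2
met2	met3
met3	met4
met2	met5
met4	met6
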