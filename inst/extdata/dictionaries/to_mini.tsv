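TO:0000051	stem strength
TO:0000442	plant fresh weight
TO:000269	β-carotene
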