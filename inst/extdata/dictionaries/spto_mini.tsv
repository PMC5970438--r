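SP:0000170	pH
SP:0000038	fruit shape
SP:0000177	compound leaf
SP:00000378	fruit
SP:0000193	stem
SP:0000016	anthocyanin content
SP:0000386	fructose content
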