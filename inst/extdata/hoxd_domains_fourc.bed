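chr2	73914153	74636454	C-DOM
chr2	74781515	75605516	T-DOM
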