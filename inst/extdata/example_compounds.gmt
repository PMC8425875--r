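glycolysis	example compound set	C00022	C00031	C00074	C00186
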