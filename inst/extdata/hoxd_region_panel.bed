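chr2	73970063	73983434	island-1
chr2	74060472	74082287	island-2
chr2	74177797	74223313	island-3
chr2	74263813	74284643	island-4
chr2	74289657	74313573	island-5
chr2	74445393	74498046	GCR
chr2	74604504	74639799	Prox
chr2	75120050	75165771	CS38-41
chr2	75413471	75451553	CS65
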