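gene	chrom	start	end
LDLR	chr19	11089362	11133820
APOB	chr2	21001429	21044073
PCSK9	chr1	55039548	55064852
APOE	chr19	44905796	44909393
LDLRAP1	chr1	25870071	25895377
CYP7A1	chr8	58490178	58500163
STAP1	chr4	67842760	67888390
ITIH4	chr3	52812989	52830701
EPHX2	chr8	27491689	27545564
GHR	chr5	42423775	42721980
PPP1R17	chr7	31688876	31699207
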