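mirna	accession	gene
miR-15a	NM_181412	Zbed4
miR-15a	NM_199302	Lrsam1
miR-15a	NM_153522	Scn3b
miR-15a	NM_178378	Iqcg
miR-15a	NM_008011	Fgfr4
miR-744	NM_181412	Zbed4
miR-744	NM_199302	Lrsam1
miR-744	NM_019553	Ddx21
miR-744	NM_001024602	AW555464
miR-1196	NM_181412	Zbed4
miR-1196	NM_177312	6330408A02Rik
miR-1196	NM_134052	Adi1
miR-1196	NM_001012450	Ankrd6
miR-1196	NM_019553	Ddx21
miR-1196	NM_010164	Eya1
miR-1196	NM_010517	Igfbp4
miR-1196	NM_001038609	Mapt
miR-1196	NM_008306	Ndst1
miR-1196	NM_001025613	Otud7b
miR-1196	NM_145457	Paip1
miR-1196	NM_183028	Pcmtd1
miR-1196	NM_018884	Pdzrn3
miR-1196	NM_139269	Pla2g16
miR-1196	NM_026164	Pnpla8
miR-1196	NM_133485	Ppp1r14c
miR-1196	NM_001081347	Rhobtb1
miR-1196	NM_177766	Slc35e1
miR-1196	NM_175132	Synpo2l
miR-1196	NM_027992	Tmem106b
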