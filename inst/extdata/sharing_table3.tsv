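# Composite haplotypes shared among two or more general localities, with
# the clade of each haplotype's localities. Localities comma-separated.
haplotype_id	group	localities
NE_WarmSprings_MLZ1949	central	NE_Warm_Springs,Sunnyside,Warm_Springs,SE_Warm_Springs,N_Hiko,SE_Tonopah,Gold_Reed
Currant_MLZ2006	central	Currant,NE_Tonopah,SE_Warm_Springs,Goldfield,W_Hiko,Gold_Reed
Ruby_Valley_MLZ2033	central	Ruby_Valley,Contact,Cobre,Tybo,Warm_Springs
Fields_MLZ2009	western	Fields,Vya,Gerlach,Ravendale
Belmont_MLZ2028	central	Belmont,N_Eureka,San_Antonio
Currant_MLZ2005	central	Currant,Cobre,NE_Warm_Springs
Denio_MSB35530	western	Denio,Valley_Falls,Jungo
Geyser_MLZ1974	eastern	Geyser,Osceola
Geyser_MLZ1976	eastern	Geyser,Panaca
Chilcoot_MLZ1756	western	Chilcoot,Sparks
Denio_MSB35531	western	Denio,Fields
Minersville_MLZ2075	eastern	Minersville,Beryl
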