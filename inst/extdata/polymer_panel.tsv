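gene_symbol	ko_id	description	category
glgC	K00975	Glucose-1-phosphate adenylyltransferase	glycogen
glgA	K00703	Glycogen synthase	glycogen
glgB	K00700	1,4-alpha-glucan branching enzyme	glycogen
glgP	K00688	Alpha-1,4 glucan phosphorylase	glycogen
glgX	K01214	Glycogen debranching enzyme	glycogen
treS	K05343	Trehalose synthase/amylase	trehalose
treY	K06044	Maltooligosyl trehalose synthase	trehalose
treZ	K01236	Malto-oligosyltrehalose trehalohydrolase	trehalose
phaA	K00626	Acetyl-CoA acetyltransferase	pha
phaC	K03821	Poly(3-hydroxyalkanoate) polymerase subunit C	pha
phaE	K22881	Poly(3-hydroxyalkanoate) polymerase subunit E	pha
phaJ	K10782	(R)-specific enoyl-CoA hydratase	pha
ppk	K00937	Polyphosphate kinase	phosphate
ppx	K01524	Exopolyphosphatase	phosphate
pstS	K02040	Phosphate-binding protein	phosphate
pitA	K16322	Low-affinity inorganic phosphate transporter	phosphate
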