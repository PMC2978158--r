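gene	enzyme	subgroup	lethal
EBP	3-beta-hydroxysteroid-delta(8),delta(7)-isomerase	Cholesterol Metabolism	yes
DHCR7	7-dehydrocholesterol reductase	Cholesterol Metabolism	yes
DHCR24	24-dehydrocholesterol reductase	Cholesterol Metabolism	yes
FDFT1	Squalene synthase	Cholesterol Metabolism	yes
HSD17B4	hydroxysteroid (17-beta) dehydrogenase 4	Cholesterol Metabolism	yes
NSDHL	C-3 sterol dehydrogenase, C-4 methyl sterol oxidase	Cholesterol Metabolism	yes
SC5DL	Lathosterol oxidase	Cholesterol Metabolism	yes
SPTLC1	serine palmitoyltransferase, long chain base subunit 1	Sphingolipid Metabolism	yes
DHFR	dihydrofolate reductase	Folate Metabolism	yes
PISD	phosphatidylserine decarboxylase, mitochondrial	Glycerophospholipid Metabolism	yes
PHGDH	phosphoglycerate dehydrogenase	Glycine, Serine, and Threonine Metabolism	yes
HMGCR	Hydroxymethylglutaryl CoA reductase	Cholesterol Metabolism	yes
CBS	cystathionine beta-synthase	Methionine Metabolism	yes
SPTLC2	serine C-palmitoyltransferase	Sphingolipid Metabolism	yes
PAH	phenylalanine hydroxylase	Tyr, Phe, Trp Biosynthesis	no
TM7SF2	C-14 sterol reductase	Cholesterol Metabolism	no
GPAM	glycerol-3-phosphate acyltransferase	Triacylglycerol Synthesis	no
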