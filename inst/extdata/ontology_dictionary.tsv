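ENVO:00001998	soil
ENVO:00002259	agricultural soil
ENVO:00002011	fresh water
ENVO:00002149	sea water
ENVO:00002001	waste water
ENVO:00002007	sediment
ENVO:00000873	freshwater river
ENVO:00000020	lake
ENVO:01000177	grassland biome
ENVO:01000174	forest biome
ENVO:00002297	rhizosphere environment
ENVO:01001057	plant-associated environment
FOODON:03411222	cow milk
FOODON:00001248	fermented food product
UBERON:0000160	intestine
UBERON:0001155	colon
UBERON:0001988	feces
PO:0025034	leaf
PO:0009005	root
NCBITaxon:9606	Homo sapiens
NCBITaxon:9913	Bos taurus
NCBITaxon:10090	Mus musculus
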