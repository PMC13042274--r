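biome	keyword
plant	leaf
plant	banana
plant	tree
plant	crop
plant	rhizosphere
plant	root
plant	phyllosphere
plant	seed
plant	wheat
plant	maize
plant	rice
plant	olive
plant	tomato
animal	insect
animal	gut
animal	feces
animal	rumen
animal	mucosa
animal	cecum
animal	skin
animal	oral
animal	saliva
animal	mouse
animal	chicken
animal	cow
animal	pig
animal	human
water	lake
water	river
water	marine
water	seawater
water	sea
water	estuary
water	freshwater
water	brine
water	ocean
water	wastewater
water	sediment
soil	soil
soil	topsoil
soil	loam
soil	tundra
soil	peatland
soil	compost
soil	grassland
soil	agricultural
soil	forest
soil	desert
other	bioreactor
other	laboratory
other	urban
other	sludge
other	dust
other	indoor
other	food
other	feed
other	fungus
other	air
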