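{
  "_comment": "Synthetic per-biome template bank: hand-written field snippets for the benchmark generator. Parallel arrays: sub_biomes[i] pairs with isolation_sources[i] and env_biome[i]. Rhizosphere entries are labelled plant and sediment entries water, matching the curation conventions.",
  "animal": {
    "sub_biomes": ["human gut", "cow rumen", "mouse skin", "chicken cecum", "human oral", "pig feces"],
    "isolation_sources": ["human gut mucosa biopsy", "cow rumen fluid", "mouse skin swab", "chicken cecum content", "human oral saliva", "pig feces slurry"],
    "env_biome": ["host-associated digestive tract", "host-associated rumen", "host-associated skin", "host-associated cecum", "host-associated oral cavity", "host-associated feces"],
    "hosts": ["Homo sapiens", "Bos taurus", "Mus musculus", "Gallus gallus", "Sus scrofa"]
  },
  "plant": {
    "sub_biomes": ["olive tree leaf", "wheat rhizosphere", "banana leaf", "maize root", "rice phyllosphere", "tomato seed"],
    "isolation_sources": ["olive tree leaf surface", "wheat rhizosphere soil", "banana leaf tissue", "maize root endosphere", "rice phyllosphere wash", "tomato seed coat"],
    "env_biome": ["plant-associated phyllosphere", "plant-associated rhizosphere", "plant-associated phyllosphere", "plant-associated root zone", "plant-associated phyllosphere", "plant-associated spermosphere"],
    "hosts": ["Olea europaea", "Triticum aestivum", "Musa acuminata", "Zea mays", "Oryza sativa", "Solanum lycopersicum"]
  },
  "water": {
    "sub_biomes": ["river water", "sea water", "lake sediment", "wastewater", "ocean surface", "estuary water"],
    "isolation_sources": ["river water column", "coastal sea water", "lake sediment core", "municipal wastewater influent", "ocean surface water", "estuary brackish water"],
    "env_biome": ["aquatic freshwater river", "aquatic marine coastal", "aquatic lake sediment", "aquatic wastewater", "aquatic marine pelagic", "aquatic estuarine"]
  },
  "soil": {
    "sub_biomes": ["agricultural soil", "forest soil", "tundra soil", "desert soil", "peatland soil", "grassland topsoil"],
    "isolation_sources": ["agricultural field topsoil", "temperate forest soil litter", "arctic tundra soil core", "arid desert soil crust", "peatland bog soil", "grassland topsoil loam"],
    "env_biome": ["terrestrial agricultural field", "terrestrial forest floor", "terrestrial tundra", "terrestrial desert", "terrestrial peatland", "terrestrial grassland"]
  },
  "other": {
    "sub_biomes": ["bioreactor", "laboratory culture", "urban dust", "indoor air", "feed food", "activated sludge"],
    "isolation_sources": ["anaerobic digester bioreactor", "laboratory mock community culture", "urban street dust", "indoor air filter", "animal feed food pellet", "activated sludge basin"],
    "env_biome": ["engineered bioreactor", "engineered laboratory", "engineered urban", "engineered indoor air", "engineered food production", "engineered wastewater treatment"]
  }
}
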