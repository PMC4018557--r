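tip_name	binomial	group
platypus	Ornithorhynchus anatinus	Monotremata
gray_short_tailed_opossum	Monodelphis domestica	Marsupialia
tasmanian_devil	Sarcophilus harrisii	Marsupialia
nine_banded_armadillo	Dasypus novemcinctus	Xenarthra
florida_manatee	Trichechus manatus latirostris	Afrotheria
small_madagascar_hedgehog	Echinops telfairi	Afrotheria
african_savanna_elephant	Loxodonta africana	Afrotheria
star_nosed_mole	Condylura cristata	Eulipotyphla
european_shrew	Sorex araneus	Eulipotyphla
horse	Equus caballus	Perissodactyla
southern_white_rhinoceros	Ceratotherium simum simum	Perissodactyla
pig	Sus scrofa	Cetartiodactyla
cow	Bos taurus	Cetartiodactyla
sheep	Ovis aries	Cetartiodactyla
killer_whale	Orcinus orca	Cetartiodactyla
bottlenosed_dolphin	Tursiops truncatus	Cetartiodactyla
cat	Felis catus	Carnivora
dog	Canis lupus familiaris	Carnivora
ferret	Mustela putorius furo	Carnivora
giant_panda	Ailuropoda melanoleuca	Carnivora
pacific_walrus	Odobenus rosmarus divergens	Carnivora
rabbit	Oryctolagus cuniculus	Lagomorpha
american_pika	Ochotona princeps	Lagomorpha
long_tailed_chinchilla	Chinchilla lanigera	Rodentia
naked_mole_rat	Heterocephalus glaber	Rodentia
degu	Octodon degus	Rodentia
guinea_pig	Cavia porcellus	Rodentia
lesser_egyptian_jerboa	Jaculus jaculus	Rodentia
thirteen_lined_ground_squirrel	Ictidomys tridecemlineatus	Rodentia
prairie_vole	Microtus ochrogaster	Rodentia
golden_hamster	Mesocricetus auratus	Rodentia
chinese_hamster	Cricetulus griseus	Rodentia
rat	Rattus norvegicus	Rodentia
mouse	Mus musculus	Rodentia
small_eared_galago	Otolemur garnettii	Primates
bolivian_squirrel_monkey	Saimiri boliviensis boliviensis	Primates
white_tufted_ear_marmoset	Callithrix jacchus	Primates
rhesus_macaque	Macaca mulatta	Primates
olive_baboon	Papio anubis	Primates
northern_white_cheeked_gibbon	Nomascus leucogenys	Primates
sumatran_orangutan	Pongo abelii	Primates
western_lowland_gorilla	Gorilla gorilla gorilla	Primates
chimpanzee	Pan troglodytes	Primates
bonobo	Pan paniscus	Primates
human	Homo sapiens	Primates
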