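species,order,category
Whiskered myotis,Chiroptera,1
Garden dormouse,Rodentia,1
Bechstein's myotis,Chiroptera,2
Brown long-eared bat,Chiroptera,2
Geoffroy's bat,Chiroptera,2
Gray long-eared bat,Chiroptera,2
Soprano pipistrelle,Chiroptera,2
Daubenton's myotis,Chiroptera,3
Pond bat,Chiroptera,3
Western barbastelle,Chiroptera,3
Eurasian pygmy shrew,Eulipotyphla,4
Greater mouse-eared bat,Chiroptera,4
Stoat,Carnivora,5
Brandt's myotis,Chiroptera,5
Bicolored shrew,Eulipotyphla,5
Crowned shrew,Eulipotyphla,5
Greater white-toothed shrew,Eulipotyphla,5
Yellow-necked field mouse,Rodentia,5
European pine vole,Rodentia,5
Tundra vole,Rodentia,5
Common pipistrelle,Chiroptera,6
Nathusius' pipistrelle,Chiroptera,6
Eurasian red squirrel,Rodentia,6
Hazel dormouse,Rodentia,6
Fallow deer,Cetartiodactyla,7
Natterer's bat,Chiroptera,7
Eurasian water shrew,Eulipotyphla,7
European mole,Eulipotyphla,7
Beech marten,Carnivora,8
Eurasian badger,Carnivora,8
Eurasian otter,Carnivora,8
Gray wolf,Carnivora,8
Least weasel,Carnivora,8
Pine marten,Carnivora,8
Red fox,Carnivora,8
Western polecat,Carnivora,8
Wildcat,Carnivora,8
European bison,Cetartiodactyla,8
Red deer,Cetartiodactyla,8
Roe deer,Cetartiodactyla,8
Wild boar,Cetartiodactyla,8
Common noctule,Chiroptera,8
Lesser noctule,Chiroptera,8
Particolored bat,Chiroptera,8
Serotine bat,Chiroptera,8
Common shrew,Eulipotyphla,8
European hedgehog,Eulipotyphla,8
European hare,Lagomorpha,8
Rabbit,Lagomorpha,8
Bank vole,Rodentia,8
Black rat,Rodentia,8
Brown rat,Rodentia,8
Common hamster,Rodentia,8
Common vole,Rodentia,8
Eurasian beaver,Rodentia,8
Eurasian harvest mouse,Rodentia,8
Field vole,Rodentia,8
House mouse,Rodentia,8
Long-tailed field mouse,Rodentia,8
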