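species,family
rock pigeon,Columbidae
ring-necked pheasant,Phasianidae
cattle egret,Ardeidae
black-crowned night heron,Ardeidae
ruddy shelduck,Anatidae
black kite,Accipitridae
short-eared owl,Strigidae
common kestrel,Falconidae
tree sparrow,Passeridae
oriental turtle dove,Columbidae
house swift,Apodidae
eagle,Accipitridae
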