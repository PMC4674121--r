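# SYNTHETIC stand-in stratigraphic ranges (first/last occurrence, Ma) for
# display annotation. Approximate epoch-level values only.
taxon,first_ma,last_ma
Zygorhiza_kochii,36,34
Agorophius_pygmaeus,30,28
Eudelphis_mortezelensis,12,7
Zygophyseter_varolai,11,7
Brygmophyseter_shigensis,16,14
Acrophyseter_deinodon,9,6
Albicetus_oxymycterus,16,14
Livyatan_melvillei,10,9
Orycterocetus_crocodilinus,18,14
Idiophyseter_merriami,16,14
Physeterula_dubusi,11,7
Placoziphius_duboisi,16,14
Aulophyseter_morricei,16,14
Physeter_macrocephalus,5,0
Scaphokogia_cochlearis,8,6
Thalassocetus_antwerpiensis,16,14
Aprixokogia_kelloggi,5,4
Praekogia_cedrosensis,6,5
Nanokogia_isthmia,6,5
Kogia_breviceps,3,0
Kogia_sima,3,0
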