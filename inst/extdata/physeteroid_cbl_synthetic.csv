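# SYNTHETIC stand-in trait table: condylobasal lengths (cm) for the 21
# physeteroid OTUs of the synthetic character matrix. Values are
# order-of-magnitude plausible for each genus but are NOT the published
# measurement table (which has no machine-readable deposit). "~" marks an
# approximate value taken from a proxy taxon of similar size.
taxon,cbl_cm,provenance
Zygorhiza_kochii,92,measured
Agorophius_pygmaeus,~60,proxy
Eudelphis_mortezelensis,~120,proxy
Zygophyseter_varolai,150,measured
Brygmophyseter_shigensis,140,measured
Acrophyseter_deinodon,110,measured
Albicetus_oxymycterus,~127,proxy
Livyatan_melvillei,300,measured
Orycterocetus_crocodilinus,115,measured
Idiophyseter_merriami,~90,proxy
Physeterula_dubusi,100,measured
Placoziphius_duboisi,80,measured
Aulophyseter_morricei,120,measured
Physeter_macrocephalus,500,measured
Scaphokogia_cochlearis,60,measured
Thalassocetus_antwerpiensis,~45,proxy
Aprixokogia_kelloggi,50,measured
Praekogia_cedrosensis,40,measured
Nanokogia_isthmia,~40,proxy
Kogia_breviceps,45,measured
Kogia_sima,40,measured
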