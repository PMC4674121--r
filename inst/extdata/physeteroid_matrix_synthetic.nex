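#NEXUS
[ SYNTHETIC stand-in matrix: 21 physeteroid OTUs x 43 unordered characters ]
[ generated by cachalot::simulateMatrix() under a symmetric Mk process on a ]
[ plausible physeteroid topology (seed 20150923, rate 0.08, 25% missing,   ]
[ 2% polymorphic). It emulates the dimensions and statistical texture of a ]
[ published morphological matrix that exists only as a page image and has  ]
[ no machine-readable deposit; it is NOT that matrix.                      ]
BEGIN DATA;
  DIMENSIONS NTAX=21 NCHAR=43;
  FORMAT DATATYPE=STANDARD SYMBOLS="0 1 2 3" MISSING=?;
  MATRIX
    Zygorhiza_kochii             ?303320?1202?21032??0?2100?0313130??10??010
    Agorophius_pygmaeus          23??3001120?1?103?3?2321{02}?311131302?1301020
    Eudelphis_mortezelensis      ?3?332?11?021?122030233?003?1331?02313?20?0
    Zygophyseter_varolai         ?333?{02}211201?313033?2301?33?1?3?12?31302?2?
    Brygmophyseter_shigensis     ?33330?112??1??3033?23012?311?3?????130??23
    Acrophyseter_deinodon        ?302?2?1123?1?13???02??10031?111?02313?2023
    Albicetus_oxymycterus        033232?112031?1303?0030??00??1310023?302323
    Livyatan_melvillei           ?3323?0?12011?13??3?030?{01}11111310??313?2023
    Orycterocetus_crocodilinus   ?01?02?11????21113002331003021113023120202?
    Idiophyseter_merriami        0??10?0?1??21112133???110031213130?012?1?2?
    Physeterula_dubusi           03?1220{13}0??2?22213?0??01023131?1?02012??02?
    Placoziphius_duboisi         0311110131??12130330?301033121?03?2?1?0?021
    Aulophyseter_morricei        0311?2{01}13103??1330302??1233201?1?0?0?20?321
    Physeter_macrocephalus       0?11?201??0312?3033???0?20112101302??203221
    Scaphokogia_cochlearis       03003121?202{12}2102?30233100312111302?123?020
    Thalassocetus_antwerpiensis  2?0112{02}?223{12}2223203?2?310?3121?1?0?01202?20
    Aprixokogia_kelloggi         220?1223123222{12}?20302?0?003?213?00201?02???
    Praekogia_cedrosensis        ??021223?23?22232?30???2?0??2??1302012?2020
    Nanokogia_isthmia            ?2?0122??23?22?3302???03?031223?302012??{02}10
    Kogia_breviceps              22??122312?2??23202?23?3103122????20100?011
    Kogia_sima                   2202122312322223203???0?1031?23??023120??10
  ;
END;
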