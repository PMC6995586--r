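>seq_1
DADCFEDFAAADCEFCAADFFDCACEDEDG
>seq_2
DAFDADACFFCEDGEDDGGEAACDCCFCFD
>seq_3
GEGADEFEFDCGFFCAEGDECACCEDFCFF
>seq_4
GFDDADADGDEGEGADDDFEADAEEFCGAA
>seq_5
EFECEAFGEACGFCGCDCGGECACCCACGE
>seq_6
CDCCCCDEDAFFFAACDGGCDGDFDGAFDG
>seq_7
DDFCEDAEFAAGAFEAAGEAEFEAGDCCDG
>seq_8
AGCDDAFFDDFEEGGDCGEFCADCDCEEDA
>seq_9
FCACCEEFCDFDEDFCEDEDDEAFFEFFGA
>seq_10
ECAADDDAAFADCEADCEEAEADAAGEFDF
>seq_11
AFECGCDCFDECAAECEEDCDFFGCDGCEE
>seq_12
DGADAECADCDCADGDEFCFGGACEGAGFD
>seq_13
DFECCFCGCDEDFADCGFGECAADAGAGGD
>seq_14
GCECGGAECCCFFECCEEACCEFCFEECAG
>seq_15
AAEGGADGECFDECDGCFCAAEAFDDGGAC
>seq_16
FCGFECFFAAFFGEDAFCFGFGEFGEECCD
>seq_17
FEAADEEADGEAAGCAGDCDFAEEGEDCGG
>seq_18
FEAEGFCGGGADFDCEFGDFFCCFCGCAAG
>seq_19
GCEAAFGACECGGCDDCAECFFCCAFACAC
>seq_20
GGAFAGGCGEFEGGDACCFFDFGFADAFDF
>seq_21
FDFEEECCEECDEAAEGEEDAACCCGGCFA
>seq_22
EDDEAEAFFAAGGAGDDDEAGFDAFDDGAE
>seq_23
CEAAFACCGEGDCDCAEEEFDCFGCFAFGD
>seq_24
DDGFACGFAGAFEDCFGDCEFEFACFDEAF
>seq_25
DADAFCFEAGCECEDFEECCDGECECFGAE
>seq_26
FEFACFEAFGCAGACAAECFCCFACEGGFA
>seq_27
DGAAFEECFGCCFDDCAEFCAEGAGEGEGA
>seq_28
AAACAFDFAEDCAGFADAEECEGGFCCGCG
>seq_29
GFEADAFDEGEEEAFAFAFDFFEDDAFCCD
>seq_30
EGDFFDGGAGAFADCEGAGCEGFACEEEFG
>seq_31
FCGDFCGCAFDFDDEDFEGDFDEEDFEDFE
>seq_32
GDADDGEAADCGGFAGFDAADFGAAECFEG
>seq_33
EAADDGFDDEGGGFADDGADCEDGEFACCF
>seq_34
CCECCDEAADACCDCCCCEEAEAEDDDGFG
>seq_35
EDFCEAAFACDGCEECFCDDEDDAACGCGE
>seq_36
FFDDEFAGEADAECEDFDEDGFACCDFCCC
>seq_37
FFDDCAAECEFCGGFDGCEGAECFCECCCC
>seq_38
GGAACAFDDEDDACAAAEGAEGAGECAFEA
>seq_39
AGACFEDAAFAEDFFCADDAADGADECGFE
>seq_40
CGFFFGADCFDEAACFEFGCFCADCGEFGE
>seq_41
AEDFDCFCEACAAAAGFFEAEGGCCFAGFA
>seq_42
DEEDEFGDAFAGDDCGAFECDADACDCGDA
>seq_43
AEGCEAGEDCDCADGCEECCEGEDAGAGEE
>seq_44
AADCEACGFDDECEEDFFFGADCEECCEAE
>seq_45
GADGAEFDDCDDDFEGCFAFECEGAEDAGC
>seq_46
GCDCFDFFEADCCDCEGAEDCEGGAFCFDG
>seq_47
FCCGFFAGEFEAAFGGGCACAGCGCGGGAG
>seq_48
GAAFAGFCGAGEGGFDACDCGDDCDCFACF
>seq_49
CFFEFGGGGADDDGADDEEAGDFGCFFGDE
>seq_50
DAEGCCAEEFFDGCEGEFAEGFFECCCFFA
>seq_51
EGAGCGCGCDDAAFAACAFFECADEEEDAD
>seq_52
FDEGDGACEDDGFADDADECEFFDEFACAG
>seq_53
GFEFDGGFGGGADFAGACCEGFAGECDECF
>seq_54
GDFCGDFAAEFDGDGFAEEGDCCDFDFFEF
>seq_55
FCEGGCAGCAFCAEFGCECEEEEFGAGEDE
>seq_56
CECDADAFFDADFCGGACAGAGADFCDACD
>seq_57
GGECCDGCDGDFDDCCGAGDDCGDCFDACE
>seq_58
EFFCGDFFGAEDFEECEEGGACFECCFAFF
>seq_59
AGDDGCCFGEDFFGGDGFEFCCEDFCGAFA
>seq_60
CDEDCFDCGDCGCCEDDGAGDAACACDGDG
>seq_61
CECADFDDEEEAGACCCFFAFEAEAADAFD
>seq_62
CDACFGAFGEFCDGACACGECAFFEAGECE
>seq_63
CDFCGFDEDFECACCCGGDACDDEAAFFEA
>seq_64
GFCEADEEEDCFGGGGGDAAFAECGEDEDF
>seq_65
FDAEAEFCCDFDGDFEFGACGGCFCEGDCF
>seq_66
AGFCFEGFCDCEGAACDGFEEGAFCEFCAF
>seq_67
AECGFFGEGDECECEGEGCDECCEGFGEGA
>seq_68
CAAFEFECGAAGEDFFGEDEDACDCEEAFC
>seq_69
GGGFDGDAFFEGAGFFGEFGGGEEAFDDGE
>seq_70
AGFAEFEEGGDEEFEAEGECEFFCCAFFAG
>seq_71
FFAFADACECEFAFAFECCCCAEEGEAEAA
>seq_72
DGEEFCCFDCFAFAAGEFFCCGFFAFGAAG
>seq_73
DDFGGFDDGCCEFAFEGFFACAFDDGFDFA
>seq_74
DGAAAADAEACGDDFFGDEFGEFCDFECFD
>seq_75
ECDEGFCEFAAGFEFDCDCCEAGFACEGED
>seq_76
AECFCEDDDEDFECCFAFEEEAFDDCDFGE
>seq_77
ACECGEDAAGFFDGDCDCGCDCGEEFDEDD
>seq_78
CCGEDGGCFEFEGECEGDCCCAFFGCECDA
>seq_79
CGFFCDAEFEAACCCFGFDDEGFCDCECEA
>seq_80
EDGAACDADCFCFDDAFECFDCAFAGEGAC
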