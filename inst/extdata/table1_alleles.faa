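>Allele_1
SSLSNKTIHNNNNYKYNYNNNNYNNNNYNNNYNNNCKKLYYNINYIEQI
>Allele_2
SSLSNNYNYNNYNNNYKPLYYNINYIEQI
>Allele_3
SSLSNNYNSNSYNNYNNNYKKLQYYNIINIEQI
>Allele_4
SSLSNNTIHNNNYKYNYNNNYNNYNNYKKLYYNINYIEQI
>Allele_5
SSLSNKTIHNNNNYKYNYNNNYNNNNNYSKKLYYNINYIEQI
>Allele_6
SSLSNNYNYSNYNNYNNYNNNYNNYKKLYYNINYIEQI
>Allele_7
SSLSKNTIHNNNYKYNYNNNNNYNNNYKKLQYYNINYIEQI
>Allele_8
SSLSNSCNYSNNYYNKKLYYNIINIEQI
>Allele_9
SSLSNKTIHNNNNYKYNYNNKYNYNNNNYNKKLYYKNYIINIEQI
>Allele_10
SSLSNNYNYSNYNNYNNNYNNYKKLYYNINYIEQI
>Allele_11
SSLSNNYISNISNYNNNNNSKKLYYNINYIEQI
>Allele_12
SSLSKNTIHNNNYKYNYNNNNYNNSKKLYYNINYIEQI
>Allele_13
SSLSNKTIHNNNNYKYNYNNNNYKNYNNYKKLYYNINYIEQI
>Allele_14
SSLSNKTIHNNNNYNNYKKLYYNIINIEQI
>Allele_15
SSLSNNTIHNNNYKYNNYNNYNKKLYYNIINIEQI
>Allele_16
SSLSNKTIHNNNNYNNNNYNNYKKLYYNINYIEQI
>Allele_17
SSLSNNTIHNNNNYNKKLYYNIINIEQI
>Allele_18
SSLSNKTIHNNNNYKYNYNNNCKKLYYNINYIEQI
>Allele_19
SSLSNNYKYSNYNNYNNNYNNNYNNNYNNNYKKLYKNYIINIEQI
>Allele_20
SSLSNNYNSNNYNKYNYNNSKKLYYNINYIEQI
>Allele_21
SSLSNKTIHNNNNYNNNNYNNYKKLYYNIINIEQI
>Allele_22
SSLSNNYKYSNYNNYNNNYNNYNNNYNNNYKKLYYNINYIEQI
>Allele_23
SSLSNHYNYNNNKYNNYNNDYKKLYYNINYIEQI
>Allele_24
SSLSNKTIHNNNNYKYNYKNYNNSKKLYYNVINIEQI
>Allele_25
SSLSNKTIHNNNNYNNYKKLYYNINYIEQI
>Allele_26
SSLSNKTIHNNNKYNYNKYNYNNNNYNNYKKLYYNINYIEQI
>Allele_27
SSLSNNYNYNNNNYNNYNNNYNNNYNKKLYYNIINIEQI
>Allele_28
SSLSNKTIHNNNNYKYNYNNNNYNNNYNNNCKKLYYNIINIEQI
>Allele_29
SSLSNNYNYNNNNYNNNYNKKLYYNINYIEQI
>Allele_30
SSLSNNYNSNNYYNYNNNKKLYYKNYIINIEQI
>Allele_31
SSLSNKTIHNNNNYKYNYNNKYNYNNNNYNNNNYNKKLYYKNYIINIEQI
>Allele_32
SSLSNSCNYSNNYNNNYNNTKKLYYNINYIEQI
>Allele_33
SSLSNKTIHNNNNYKNYNYKKLYYNIINIEQI
>Allele_34
SSLSNNYNYSNYNNNNYKQLCYNINYIEQI
>Allele_35
SSLSNNYNYSNYNNYNNYNNNYNNYNNNYNNYKKLYYNINYIEQI
>Allele_36
SSLSNNYNSNSYNNYNNNYYNNKKLQYYNINYIEQI
>Allele_37
SSLSNKTIHNNNNYNNNNYNNYNNNNYNNYKKLYYNIINIEQI
>Allele_38
SSLSSNYNSNNYNNYNNYKQLCYNINYIEQI
>Allele_39
SSLSNNYNYNNNKYNYNNNNYKQLCYNINYIEQI
>Allele_40
SSLSNKTIHNNNNYNNNNYNNYNNNNYNNYKKLYYNINYIEQI
>Allele_41
SSLSNNYKYSNYNNYNNNNYNNNNYNNNSKKLYYNIINIEQI
>Allele_42
SSLSNKTIHNNNNYNNNNYKKLQYYNINYIEQI
>Allele_43
SSLSNNYNYNNNNYNNYNNNYNNNYNKKLYYNINYIEQI
>Allele_44
SSLSNKTIHNNNYKYNYYNNNNYKKLQYYNIINIEQI
>Allele_45
SSLSNNYNYNNNNYNNYNNYNNYNNNYNKKLYYNINYIEQI
>Allele_46
SSLSNNYKYSNYNNYNNYNKKLYYKNYIINIEQI
>Allele_47
SSLSNNYNYNNNNYNNYNNYNNNYNNNYNKKLYYNINYIEQI
>Allele_48
SSLSNNYKYSNYNNNNYNNNSKKLYYNINYIEQI
>Allele_49
SSLSNKTIHNNNNYNNNNYNKKLYYNINYIEQI
>Allele_50
SSLSNKTIHNNNNYKYNYNNNNYNNNYNNYKKLYYNINYIEQI
>Allele_51
SSLSNKTIHNNNNYKNYNNYKNYNNYKKLYYNINYIEQI
>Allele_52
SSLSNKTIHNNNNYKYNYNNNNYNNNNYNKKLYYKNYIINIEQI
>Allele_53
SSLSNNTIHNNNYKYNYNNKYNYNNKKLYYNIINIEQI
>Allele_54
SSLSNKTIHNNNNYKYNYNNNNYNNNNYNNNYNNNCKKLYYNIINIEQI
>Allele_55
SSLSNNYNSNSYNNNYNNNYYNKKLQYYNINYIEQI
>Allele_56
SSLSNNYKYSNYNNYNNYNNNNYNNYNNYNNKKLYYNIINIEQI
>Allele_57
SSLSNKTIHNNNNYKKLYYNINYIEQI
>Allele_58
SSLSNNYNYSNYNNYNNYKKLYYNINYIEQI
>Allele_59
SSLSNNTIHNNNYKYNYNNNNYNNNNYNKKLYYNIINIEQI
>Allele_60
SSLSNNYNYSNYNNYNNNNNYNNYKKLYYNINYIEQI
>Allele_61
SSLSNNYKYSNYNNYNNNYNNYNNNYKKLYYNINYIEQI
>Allele_62
SSLSSSCNYSNNYNNYYNNNKKLYYNIINIEQI
>Allele_63
SSLSNKTIHNNNKYNYNNNYNNNCKKLYYNINYIEQI
>Allele_64
SSLSNNRNSNNYNNYNYKKLYYNINYIEQI
>Allele_65
SSLSNNYNYSNYNNYNNNYNNNYNNNDYKKLYYKNYIINIEQI
>Allele_66
SSLSNNYNYSNYNNYNNNNYNNYKKLYYNINYIEQI
>Allele_67
SSLSNNYNYSNNYNNYYNNNNNYNNYKKLYYNIINIEQI
>Allele_68
SSLSKNTIHNNNYNNSKKLYYNIINIEQI
>Allele_69
SSLSNKTIHNNNNYNNNYNNNCKKLYYNIINIEQI
>Allele_70
SSLSNKTIHNNNNYNNNNYNNNNYNNNNYKKLQYYNINYIEQI
>Allele_71
SSLSNNYKYSNYNNYNNNNYKKLQYYNINYIEQI
>Allele_72
SSLSNKTIHNNNNYKYNYNNNNYKPYYNINYIEQI
>Allele_73
SSLSNKTIHNNNNYKYNYNNNYKKLYYKNYIINIEQI
>Allele_74
SSLSNKTIHNNNNYKYNYNNNYNNNSKKLQYYYNINYIEQI
>Allele_75
SSLSNKTIHNNNYKYNYNNKHNYNKLYYNINYIEQI
>Allele_76
SSLSNNYKYSNYNNYNNYNNNSKKLYKNYIINIEQI
>Allele_77
SSLSNKTIHNNNNYNNNNYNNYNNNNYNYKKLYYNINYIEQI
>Allele_78
SSLSNKTIHNNNNYKYNYNNNYNNNSKKLYYNINYIEQI
>Allele_79
SSLSNNYNYSNYNNYNNNYNNYNKKLYYNINYIEQI
>Allele_80
SSLSNKTIHNNNNYKNYNNYKNYNNYKNYNNYKKLYYNINYIEQI
>Allele_81
SSLSNNYNYNNYNNTNNINKQLYYNINYIEQI
>Allele_82
SSLSNNYSYNNYNNNNYNKKLYYNINYIEQI
>Allele_83
SSLSNNYNYNNNNYNNYNNNYNKKLYYNINYIEQI
>Allele_84
SSLSNNYNYSNYNNYNNNNNYNNNNYNYKKLYYNINYIEQI
>Allele_85
SSLSNKTIHNNNNNYNNYNKKLYYNIINIEQI
>Allele_86
SSLSNNTIHNNNNYKYNYNNNYNNYNNYNNKKLYYNIINIEQI
>Allele_87
SSLSTNTIHNNNNYKYNYNNNYNNYNNKKLYYNINYIEQI
>Allele_88
SSLSNNYISNISNYNNNNNYNKKLYYNINYIEQI
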