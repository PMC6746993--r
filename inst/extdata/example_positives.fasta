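>pos_00001
SCELSAEELKAVDDIRCGYYSINSQQGGKYASSNCQVTMNNCKQVKLPPSKYAGSYQQYWPVETQEDM
>pos_00002
KRELSAEELKTVFMIEFSLLMLEVPTTYWIHSSYTEHFTEEDDNESSWNWLFLAMHHNQIDMVPKNWMFNAIVIFCGKFI
CAVDWPLDPDGNMFEMYIFHNCTENPQSEIYNEWGYWETM
>pos_00003
IFELRAEELKAVTQECMLDIWYKFIIEAMDGYHRYALKEHPYKVSTYCFKRMNIVHLDTKCCAKVYLPDFSMRAMMPRHA
QPQY
>pos_00004
VPELCAEELKAVNRGSMAYPDCNQLWEAHDKEPGSEFHTLDEMA
>pos_00005
GDELSAELRKAVDLKRRLIHRWVKDVDEQIFKWICYAMMPYFTGPVEWMWGDCAMVLMFTIFCEFNVEWPEYHFTGINIF
HKPVYVEQRCYMH
>pos_00006
FPELSAEELKAVDYHWTTGCCHISHNTQGACGQCCQPGYRQGMAAMSIVLAVMNIDMMHTINMTFLNMNRKVYEGMIMPG
SFRHLSMIGGGPSENWSIEPVNRMKAYGAWRNMGEMITY
>pos_00007
DKELSAEELKASIVEESNQEWVCSNYYMTNGSTSFHI
>pos_00008
QEWLSACELKAVYDMIRQWYPNYWLDTYKGDKFEHPEAYASECRRYLLNLDKFSCYYTAQRKDREHQK
>pos_00009
FNELSAFELKAVSQYDCNGQKCCAGCGDGLCKPQHRYCTVDPNEHKVFNTHLRCPYLYARHGIWDF
>pos_00010
PYELSAEELKAVLQKKYKDSRDCLCPYIGNEKIYYTTAPGETA
>pos_00011
YYELSAEVLKAVTKCSPDILISKQQVRRLRCVDYDFTGLLQPDFHKSELCMTMGWEHWTDVWEENDMCVDVNMCPSGVLP
FFFVEHTHWC
>pos_00012
EKELSAEELKAVFPVACVGERHVQNCHCWEDKRWGKQPCMYGRYCEELAKSSCYNRCYCTNHNNDYPDRQDLQVKTWQKY
SDEVTDYSYNIVTNTDMCSSCMPHDKNHYLSFGCILEWC
>pos_00013
ILELSAEELKAVDCLAMAMEPGSTLMLYPRIDYRCEVLLLRFVYTNHRYADKVNILCVCRPIAVQEWPTCHTVNQMPEVL
TAHVRTFTSTIDRCQHKYRSSGLPWPYK
>pos_00014
TKWLSAEELKAVCSTEPKRKVAMDEWSWYMDSHIKIDPTNHLWYNTTVYLQGWYPR
>pos_00015
NFGLSAEENKATVDMWLHDWEIRHLMGKDKAFWEFSHGP
>pos_00016
FGELSAEELKMVSDKVKMATMAHFTWIYYVKRHAEIQGYPKQQWQ
>pos_00017
PRELSARERKAVMVHMVINTFA
>pos_00018
KRELSAEELKAVPHCLQCREYEPHPASLMRMHNSTVIWIRFAFFQSYTFHLVFRVRKWPM
>pos_00019
ESELSAEDLKAVKEADQFPEVIMFNMETCFENNCFPTRTEPSLADNKKIASTYRRYEAADVTPICIFGMCTTEFAYCSLC
KFHYKHTCFACSNKMAMASRMDTICQEF
>pos_00020
LKELVAMELKEVCTHFDSMKQEDRTKTVWLDWHIVPRQGQMPVMDM
>pos_00021
DLELSAEELKAVIFNFGAFAYGKDWAPPSPFNMYMLDYILKRPFIPTWSLCYEAD
>pos_00022
CKELSAHELKAVPIWDRDWVFVMHPRQRGAYRHADPRTSVVMFALTDWVQQYVMSTHSPWCRRPVHFFCEDVEDWSNHEV
SVCHLIWFKCYVAQEYEPFASHTKWEYYWNVYPKFWGYRF
>pos_00023
KDELSAEELKAVWSGMTCDTHIQVDHSDIWGPFANVQWRTEHHKHWSWSSAFTAHDGIAALRWVSQVFKHEPRCVFRTAK
NKEVRHLSVDHEGCDNDLEYCMTYTAFILRRFTT
>pos_00024
VNKLSAEELKAVAFNEGFREHCGS
>pos_00025
PLELSACELKAVRAATEFYMKIMYNYIICMKENVCSSWHEYQQIGVPYQGVRLECSDDFARAKVHMFSPGFDIQFCDFVK
DWNVHTEGQWQLWYQDLKAMHSF
>pos_00026
FHHLSAEEGKAVWKPMEVTRGASPAYDDYFYFHCLQGCHVSNFRLPLYMQPRY
>pos_00027
TDELSAEELKAVLIGFVAFIMLVWMSRSAAAPYAAQFDLCASVFVNWATQAKGCKGIHHTLRANFPRKANCQVRFAYETY
QSMDCKFHGFWDLILIGKMCCRVTTTYTLPT
>pos_00028
GEELSAEELKAVCMATRVHIEP
>pos_00029
ANELSAESLKAVKIWLCDGRMLPCRSSPDPNMRLYGMTYTKWMEPFITTVDIMFHQHEWRWAYCKHNTDYILANIQE
>pos_00030
HIELSAEEYKAVMQKAWCPFMQHEDACWPRNGYPQNTTNIGLQRQSGKMIAVEMYELDYVFQMQQWMYSTLCWIPCTWEG
HCWLRILVMITALRNECCAITGTKCQMHIDDYTAWA
>pos_00031
CMELSAEELKAVFDVEKSDFKGLIEKPTNHYNWTRDTGEVAKDCLFDTIIAIRLKTTIHRS
>pos_00032
DEELSAEELKAVLWIWNQCLPENPDSQFNTLIMQQNQKICWNM
>pos_00033
HGELSAEELKAVSMHREIQFLTITECIVVCVMGIELDWNEWKEAYDWHQ
>pos_00034
LLELSAEELKAVGAMCFYNRKTMHEVKTENIWSTPMVYRSNLVDWSDEVETGVCFMAFCENI
>pos_00035
YYELSAEELKANEYSHDSFFNICVIMKRYTKEIH
>pos_00036
EYEPSAEELKAVTCGIPCDMLTWFTDGWVFAVLPWVSVLWY
>pos_00037
NFELSAIQLLAVHVECLPNYHSFVTHFQQWQDWVMDCISAMRYMSVCLNSEKCCTRCIYHKNHYFQCVRSCNQSELR
>pos_00038
VVELSAEELKAVISCHFHRVNADNSET
>pos_00039
AMELSNEELKQVGVVASKNYPLGVMFSQEGNDESWYHGGFFERIKSHTDRYTSIQ
>pos_00040
AFELSAEELKAVHIYYATFHTVPETDSVMNRCERDITINWLICKHHPQIRNTQMLIRCLVKVKSSITVAWFPGMSCYYWQ
IRGVAMY
>pos_00041
MNDLSAEELKAAMRMSQKNMSAMYNYYNTGYSTNIANCCLPYLCVKSQWLAFFMMYMDHYAVFELDQNPQMWLMNRHYIW
VTYQFQMWTWQMYQHAIYRFKYAMI
>pos_00042
ALELSAEEPKAWYTGQDIADVNGELSYTVQEEQGWIT
>pos_00043
YFELSAEELKAVWDDSAFLGYPKFAKMGIRTFHFPFYNCWFFPPAHTEGWQHRYMGNSFWQAFGVNEVVIYSWIAECCGR
CKNAEEQIMTCKRRYYHADNWGPEYHHIGEW
>pos_00044
TPELSAEELKAVEQIWGIHSCLLQVPWHATQVEHRIWRAETPYHRFEGFDAHTKHTGEFYPSLGFAWDNWTDKSPNVHTF
VPCNPSLS
>pos_00045
VRELSAEELKAVHAEWPVQMVEA
>pos_00046
YAELSAEELKWVGWKFFVVNHRVWYIVIILEWGINLKTWTNTCNVTAQIHQALCEVIQLNIHQKDAVMFKLFRITMDDFW
LNDYPVLYADDSKKEMFHYPDNYCKVSPEFVEWGDDV
>pos_00047
TTELSAEELKAVFQMILRCISKCAIWNPGDDAIVMDFVDTESHSISYRDVQHIPNPHNTFCQPLNSWNL
>pos_00048
AWELSAEELKAVSSKYHVDQSHAQCPSCDDKCLYQSKCTRINPKVGVEPVTHWLISESFILHYQLEGQRPKPAKWCLCCD
YQELLGRGVSNDQTKRCFSMLVYYYYNQDLNRKKGFNV
>pos_00049
GMELSAFELKLVSQWEHWAYRYSENISITIHHGHHFFHNKYPNSIVRGINYAHIQTGGEWESNFFVRWQVYCMPGYALVH
PLFCKEAMGTRPRSRFQYKWSSHLSVL
>pos_00050
RLGPCAEELPAVNYCSMTCREGHPHGVTMEFYHWHWPRSHIKKIREFDLYLHGTHDKYFKMAECQDIHTERYISKLSHTN
RLQRCTNLDVNYHTMWESLVYHARCS
>pos_00051
MEEYSAEELKAVAIKVGAWWDDYRHNNNALHELQCYDYFRSGDHNHPSLLTAQKMPPLEHAVQHNNKK
>pos_00052
LCEESQEELKAVNNRFPPYPAMTMCEWVGDDAQYPRMDHRTCQKF
>pos_00053
ALELSAEELKSVMAACNYSAHNFVC
>pos_00054
PECLSAKELYAVFWRNKRWPDVQHH
>pos_00055
MLSLSAEELAAVMLFSCSCCD
>pos_00056
QAELSAMELKAVVSQDRETAFW
>pos_00057
YYELCAEELKAVGIFTYNTPYFHPQQEVNIFPRQMEYDQT
>pos_00058
NHELSAEELKAVEYLEHVCGM
>pos_00059
ACELSAEELKAVRHYRHCIPKRPNCTITTTQYQIDQPLMTNIVHYQLLHGLNTRMLIGMRYEFLKLEAACIQVPNNL
>pos_00060
MEELSAEEQKAVMQCHPAEEQYATACPQE
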