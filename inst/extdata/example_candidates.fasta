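>cand_0001
RGELSAEELKAVPSLAFYCCRPLGGLYTEKEMCSEKSDVMKGPGQAPRNMKAREQMPWYYDVD
>cand_0002
GGELSAEELKAVQQRNLEPWEMCMIKNAFPWKLENEMASITDEGDHPIERSDVHSTQTK
>cand_0003
LTELSAEELKALLWVYRSYDHGNWKAAPCSIHRKHKVASMNADFPNNCPVHYCVRPMMVLYSYVYEVPEWGAKQKGMASD
WGWIAHD
>cand_0004
SRELSAEELKAVYPKRAVDARHLWKSFCAFTYLKCYDFKE
>cand_0005
WWELSAEELKAVKVAGITAFGPPGRTNAGIPEKFLNSVHSMEYCKATWLHFFRNVHSMDDRPHTNKYMEHQHNPCLWSCH
MVQAS
>cand_0006
ECELSLDELKIVTEYAHFVHWGYH
>cand_0007
VEFLSAEELKAVGPDLRWTCHVPFDAYTTLCKNCEGLLSDSEMGWMHRIRPRGKETNLTTQAVKDKICWYWCCTERDYYM
RCNCHPDFSCAQAGAAMIQIACNFGIQHN
>cand_0008
SAEVSAEELKVVMGGFDNRMKCGDVVYEICCTVASVWSDYQQTPMYQCQQCQMKSPEKWWMYFHNAKPWHMKNNC
>cand_0009
CQELSAEELKAVIPKPFVFGGYSFQWMNEACWDQWHPESGHQQVTLWQKQSWKIERGGAINMMEEENEKDIDPTHLTHHD
MGNAVILMGKTPIICMWYDPCKSSAEG
>cand_0010
KYEQSAEELKAVQSKKLRTWHSEAMITFWRDRDAVPLAEKYHGCSYHFAMFIGGDKFNSAIVHYWWGHRFNWLCFLVMKH
YYELCHHLCPYYDCTT
>cand_0011
VIELSAEELKAVTMNYKESLMRHMNG
>cand_0012
IMELSGEELKAYPRLQTAYDSEKMMDNSVLWDDHPWHYGHHLKPSQTMDCKRYPMVMH
>cand_0013
VYELSIEELKAVTRQGFPVPM
>cand_0014
HWLLSAEELKAVELVQRRTQQEFARDMGCVALDLAIQYCFYRFCLFRKINLHKMECTPNGWWSFVYEDETWGTTMMLYNF
TIPLYQATRHFRNREWFCWGWPVMECNTQYAEKW
>cand_0015
QSELSAEELKEVRNYEDEHSSTNKRTAIYADTPEVFDPKEKQKPLGYWNKCCCKEQMWYMITLIDKMMKRGEGQAVPFSL
NIDLVASYVWDRDCPNKYIYKGCQT
>cand_0016
QHCFCSFPGTQPLFRFYDKCPTGVQGWKISHHHFHNEQWVLHKQLHPKL
>cand_0017
KEAEAAHELANRMKARGNWAMWGFQTRAVSEDTFWDSDPNKTYRGQQPHDPWDCFWVEIE
>cand_0018
DNLDNKFKTMICPSGSGLPYIGQFISWYCYCPRMATCLWPIMCLSWAMWVVCEALLSLKIKMSSELKLSSQYVKADTFEQ
LKEGTFVPEGGQLNTLQFSMESWKELMATEEFNNYDPRGQ
>cand_0019
DTAGAAISILRGKIHQKLNKNQKECWACETRMWIAAIPVWYTAVNIWEEKAVVHAVLMVVECALA
>cand_0020
VDAVKVGQVEVGAYIKYAAGYCVPDWWEEHAGGYTKICSTEKRDVLDGCYVIMLS
>cand_0021
VKEKWAGNEVYRVKKQVLNGENYGEAIHVKALWMFEADLLPEMAQFILWWGAYG
>cand_0022
KQKVTAKEQYIMLGEHEMHEAPLMTGKKCTWGNEMNILSVVNHKKELAKSYDRFCVPHVGHAAYHKSCGEMDQSINSWKM
FGHFADWDMTLHEIACEVYSGYARSVG
>cand_0023
SGMADYTQSDFFPHPKDMSYVNAYCRMDNPAYEWLKGVAWEEKPLHCVLWHCVSLFANTANLMCIRRL
>cand_0024
PHLDLNLQEYDINDSVQVIMMQLWRDMNAMKDREHSVDRSAYPDDETSESHLFRFMAIDLCNWVLEEPAKLHIKMEVSRI
SREVVMLMPVCQ
>cand_0025
CPVCILYVMGEAIRMLGDAMFNIMELQCTEQWEVTSEYKHLGYLVKFYAEMQEFMGKDSAICDGHWTGWDSNEAACMSYW
FPKSWETFMPSKALTEQHNLEATYTCVSETELQVCYW
>cand_0026
DFMHKPSMVCSHSWSWEDGWLSELPVGMIKAKPWKAEQFIYLQLGSEDDEEMLNIKHVWGYPTKWDNHRKSYKYEFTVLE
SYLSFVFIKFRAKTYQWI
>cand_0027
HKTHSEQELCAEIMLLKPHGSWPWHCALHNYPKE
>cand_0028
PEDYYKQRAEGTLPYWYGVAKEKM
>cand_0029
SWAVESATKGVRWNKLAAQAFAGTNIKPCCPCPSLQVPREVVMTFVYKEWSVALLVNWYAGNHMKWVMGFSALWLSLDRA
HCS
>cand_0030
HMGRSEWKYAQMHTRGAIINWNHSDKSWESYRVKDSLRSGYGPLYSNKGIRWKMPVPYSLILKHRWNTWENAHYHCMMYL
>cand_0031
DEPEQWRSHDKHAGHKMLVEEEGHCKFNYGQIMVKELCLQWMHK
>cand_0032
GRLNEQGCLFSSAEVNYYMSAKDLAFVFLTNLSS
>cand_0033
YKARNYNKVCPTRNVHRKIIDDYWWKDSIFYPSLSEWH
>cand_0034
PECCECGQSFILSHCGGKPKEASDINAATQGWNNDTYTLYFHVEVLAI
>cand_0035
ETHTGCNRQNTAWETLKMVKLDECVWMAWDWASLSLQFQEEAIRWEGLKYKRQMDFKVYLLKWAANAYTAYYACLWDTQE
LYS
>cand_0036
KPVTVVCPYYGTHVAQWEFPIWKWREPLDWKQPNHRVPWVTPEETYCKRECMKEKECPNQPNEFNREKCDLEAAGGHEKL
WNVSCAILMPAM
>cand_0037
IAKEFHLWELDQELAEEIEEAPFPLCPPHSGVMKFLELKYGGYLQKKQGTSCDQRKEDPRVLKMSEHYQMESKINVEGWR
GWE
>cand_0038
SYNGVKHSHPDNAVALKMASHLMPKKRQKMCTLLLPMEPWGNYYSCFWRTACSSSVEFNFMIEYDWTNPFLWAKLTLCKD
QRRQ
>cand_0039
NTDEFPTHAPTLYIVAADCPEPLEELYDITYNYHKSGQHQCGMQYKAHPAPCKELENPVNKYTPRKNQSYTHMQFFRHIA
GPMKVKYWMGAHGV
>cand_0040
YTDMHSIAMAYMYSTAPCVSRFEHEWIVKINEVKEDEPKILRRQFRAERVPKMLRYNLAWI
>cand_0041
MKTXAYLLVVAGGTTSSDDEE
>cand_0042
MKTAY
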