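>rspL|regulatory synthetic stand-in sequence
MLGKIVKNQLEFEAEIERVERLKRADGRQNADLALPMDSNKFMPVAIGFSMGLVAIIFSY
ADYRFVKGMKAGEDFLHQHRRAVLCILIQVKMNTSAVAVVKNIPFDYAALGQEDRCDSDG
MTWDIVYIDVLMREELRTKQKEPTPEDSDHLIPEGARKRVTTNAKDGLQDAEPESRQPNK
INL
>rspR|regulatory synthetic stand-in sequence
MKIGATDGDSELQPSALPQENYGHQDHMSEPLLIVAPKFEHQHINMRVKANVWEWGDIRI
QPGSDLRARWVSLSGNTEKKDRGQLMKRDEYGDLITILQGVIQFPALQKMDVINPSPGEI
ASIFAASKTLDEAIICEMWVRSGALEYDAMIREARRLLEAAGLLYCPAQYRKNGGETMVY
RGSERATDGQAPTSAPGPSMAYRSRYRIVKMYAYTAPDCQINEPVMNRADRCNIGRKAAI
TCVMQPKEIAGSVGGLKLTPERPLNTQLFISLQAGELLLNVLKESNHGRGFQSKANDMER
WK
>rscV|structural-conserved synthetic stand-in sequence
MNLGGMTFGTSLGEEDIAINRGVGGLGSIEYDVPRKLNTKPKQDAMRKDPMSISKQMTVI
PVAEKSNIARGLVLLFLVGRVGAPQLDTTCLLGNKDDALITQFWRLLYASTCESSTVASK
EENAPVELLQGVLSPGNIGGEVVIELGLNTYHLYNAAAENLIDIRAAPTRTQVALSVESI
HTEVAIGCTYKAKFFAVLVIGKFADRKKSNTGPQGIDKTMPEANLRTVDASQGKEIRLAV
DKTVAALAMPLDGKYKNFAESPKSKHFKGQMERGRKRDILKTSIIRNLEEAHESLTNLLV
YKVWATVEAFPSVGLGVVGVRRSRRKHRVGRGVWPFLVEMKEPQRVWRHDMMEAGSSYPE
NMTSSEKYYLQQEKVQPSKSASKQLPLPDDWDFDYSGKCNICAELQAQGTLEAQINKSLE
HVRTFDPQFGSHLELSRLYSPEVEGYHFAPKVAGLDSPKEESGGTNAFLDFFMITKLLNA
KMHEAGYKPPRIHQTQFVQRLVYDQRQESSVRKVNSYLGVAGPPWEKAVLPKFLSAAIRK
GPAANRSAIEAAEYIANTVESMQQNLQDRTPITLCGEFGSPVPDLALKNPVEYIEVAFNR
RKYGGQTQGQEVARDVLDRRGKPNLVLRQSPCVEQIARQPVRWTAGKMDRNLRSSQTDVC
RNPLEKTANDDEIYSTFFWNSISVENSR
>rscN|structural-conserved synthetic stand-in sequence
MCKSKRKEVFVRSKSRVRVHVAGSQHGLDKTDILIALLDRLTTLLYMGPTTCNRGIIHTE
GLGLCIGPGSFEIGAEDAGKEKRVDAAIKYTEFWSEGSGDRVWKNVMKPRCGIAENIDKL
QFDVGTEAKLLLAFTYYMEVQGVLEHLLTQQQFQDGRATKQNYSYSVDEACGEEHAFIAT
YLAQYICKSRSLGCPLIELAEESLGATVKLSRLDTRISARNEQGHSNLSMDLNRMEQRHS
SSQGFDADRPTVMYHIGCRGVPEPKPNYILAQLMPAGELNWYVGTVNPRDRRGGFAYVKS
SLGKWKGFGYTYTQPARLLRMKGTDGAADSSAYVHAHNLTVNNLGEDQISQDTDNGEHAT
TTDMNPINHIVNANYTLLDLKERWDDNWRVGRGTLLHLITKANIYVGKSGECEPFTQAAL
INFQSVRDCMVQTKGGECALRA
>rscQ|structural-conserved synthetic stand-in sequence
MTVYSTDQIFTTEFVAKEPHPIGIVCKLRSYRKLTILPFDEKENIACDQRTLAFLWSTSR
FKVEDAKDYYVFYRYHKECLIKQHDDNKIDDSRCWPEPGPKALATEAPNNAAYFSRTFQL
QIARKYLGPGFGNTPIFIVQFARTSPRHFVGIESGSKTKNKSGRRNQNQATKLVGILRTG
PREEANPAALQVQFIDLSLGEPVIFFAWILVSKQFSWHVLYTRSALWNYRGSSVKSPQCT
AEEEVSLDIKAIAETGGERMVFMHESCPPTKSGDSNYLVGSFDVKLDDAALELLYRPKTQ
KRVREKIDEYTLTLKVAW
>rscR|structural-conserved synthetic stand-in sequence
MDDANDVLKKYSINQSLTNSLREAAGARLDRKTVKDGPAGIGLLELSMAVLILPRGILSD
YIINDTLLDVGGPLIFDIPLADFPPEASIKISLTLDHALQTHEYVVQLAILPLTMISREE
ITFATIQTVELNKGFVAEFSRKLLSAYRAIGSFPQLIILKHSPEMFFTGRRHKLMQSYKE
ARIMQELSYRISTHGPVLGISSANYINLKLKIMHA
>rscS|structural-conserved synthetic stand-in sequence
MMASTFEKWRKLNPTEPAPLPYINEDTGGKNERQATNRILLKGVTQGVYYISAFLVDARL
IAVLMMRANPISGQSFYVNRGEERIVLA
>rscT|structural-conserved synthetic stand-in sequence
MLEFGTGYLMIEKVIDAESEMKCSASKGIMEAYIENLWKNAFIGRGAAVEADAHALNQIK
NASSAGDKKAARWEPWFHLSYGQVPDFHMDTYGPWQFAEMNESSACMQNSLKEGEENHEL
SPLIVRYNVGYTEAPAYLSGAPELAHAFDEFQRKTPLDIEISQGMWGALYLWETLEPLAF
SEKPSKDGVEYAHAALMMQNSQYAIIFKAYVRELSECTRGDRSYEENQFYGTLDGPPTPW
VLERLRTLPEIAEAVDVLCVEE
>rscU|structural-conserved synthetic stand-in sequence
MVVAILLAALRRSEPLAGDIVWTPLIIKKELDEKVHGPFNMVVSAFVASDQWAPFIHVLD
LDFTDTALIDMMDWDLSEELMKFTRTITSSSKMMIQMLARKSSVPPLHVTGAHPNALSFV
RLMTIRKDFKILHTNIIFPATAYTRHIRAVTIPAVQMPPKLYGMDGQACELEGTNETRAD
LKQKYKMYEARLQAERFVIMISCADRKLIIATQRMGKVVKNLTLFYGTFEKASAHIELKD
RDGDLILVSEFTALTVPEQKRLQQTMAVIGEPYKWPAIATGTPQINVRKEAIVLSYCLVR
QESETVLNQDLYKNAKSGCAGPKREFSDLAYAGLVGTYSANKRLTKIFS
>rscC|structural-conserved synthetic stand-in sequence
MLQMAKIVTIAGCLLIGEYKFYVQEAESSNVPGALLGGPNARIQALEKLLGVRTVAVQMG
VDDIPRLTVLLAYLKVRILYVVYDDEPPETIIDGLYHLGGAYEAFEKIKDGFIQNAYLGD
DVWSSHREEGIHYQDGRAFEGAHRSSTSEDDIATQKLSKRCRKPVAFWDQAEHMPEGGHY
LAIIQIQIGYLVYLGHEPELALPLRDDNDLVDIKVGSSSDTWLTTHYVQPGEDAANFHGS
GFSIAHRIERNYVEKRGKLAEQRLFQEVFLGGASLGFSILFGQKIQVEMWDKPCLDTNFT
KLSEMWIQEMANFAQTSLENLLMKDYLTKPLNFQVEILGFSFFMSKYTQIWFQHSLHVVM
LVNAVVIAEGPFEPGQQLLSTDWTTAESTWSVGFKRLYNKSTLSATEDLIKQAESDLKFP
YFNETEELPRIEADKELQPHQAAKEIEIDDDNEGPDDKSALRTLLNLLTKFHNHSRALPS
LHDCMALLTQQEKAVASNKQTCRKIQSPSKQSIEVRLGIPSLFPTGGVEKGEVLLLADQR
IIISRKLDTSYSFLDLTRKTRGYYKLHLILANPNLPTCIMPDKQPTAWMNNTLTTIDGLN
L
>rscJ|structural-conserved synthetic stand-in sequence
MSPDQFSCPLTGIRLWAVFDYAPSMTLVAVQNSDDKEEAIRITDLKDNLDYLDCNPKDPT
PAMEQALLKTVPLGMAVITRPVELVEGNGLVSTANYYKAGDFIKKSYLLLLAWLNALNII
EWDTKVAIRKEGERFGKFVCFGGLARPYLKSIEDNAGRADRDDDSFQLGSKAEYFDLRGA
AQYRVAYEKLKHTNLLEQIFLCDNHPDKLIESQVLKGSLPKNGPEAEISLGRATPSIECA
VQLF
>rspA|structural-nonconserved synthetic stand-in sequence
MTGEFHDLNFEIVNTVEILTYNLEQGGINFEIQPFWTLAPRFDPTPHDLADIAYIYLNAW
SSQGFHQIAKTLANKQAKGELKTSQLTETLKETKKKGLTKAVPSGTVTGFRAFDTGRTEF
ACLSEDSTEVHLEWRLPPGSQSDEQSFPKALVARRTPSEHFRPTPVEFFDDWSFLPKELT
VEYEEAVVMESLLDDFSTLACYSVRSDASFPWRAVIQMHTPKTSELKEIHRLAFDAAMEI
FAEGKSPGVREQVVGFGS
>rspJ|structural-nonconserved synthetic stand-in sequence
MESTILETEIERMKLMDFQSLLFEAGAHHFLLEYDLAFCRQMAGRQLKLPHVLYKSLAYA
CGLEGVAELEESDAQILSDRDLDKVTFIIDICDLYDIGLLLDLQQELSKGLTLDALYS
>rspG|structural-nonconserved synthetic stand-in sequence
MNYAEDRERAEQEKTLEFPDLIHGADERGVAHFEMIHSYGQAPDNCKLRAAQMEQFLGIC
KSLPLYMIHLRPPNERTALPQTPPTAMQMVLLLMSVLKLELIDDGRETVRIACTALGPSK
IKAVKMNQQKLLIETARAAFGD
>ropE|effector synthetic stand-in sequence
MNAYVEASVEGVYVLGFAINTGIGDMDGWELKGWQIAEFGHVESGFLAGNTLSEDCGNRS
TFPAGYRLKWAMDNLPVLQHGGTMLARGLSMKCMESSANKWTHPRVEILPGGEVNQCAGK
CARNGGTLNSTALRIGCQAGVNEAQGERQVWLFAGWRVFGEKLAEVFAVPVEETTMDSAL
WSLAKVNVMMEFSLDSGDDLMFSVFWRVLHQDQGFIGPVWAPPPPQMVFDRDENYQLDNV
KEAVVYAYVADPILGDWTAQIPLNTLCYIMVKPGPDETSSLATNIYGKATEVVTMRALDT
EKLNAKSMTRAGKQREKEILVVGDRLALVRGYARVAVENVQLKMLDLVSLYEVKKILMGP
PEGASGDEQQRVGRWGWYAPSLYPNVGAITEWPLYAGRAKDSIVGCQIRNDAIESERRFG
AYKGCTTANGMGGEVEAFVGLKLAISIDPIETSKLIKFNSTDSSLLPERLDNVFSPHNQE
LLEQTPPELGLGIAKRLYGGGLKVETIANFLSAAAWLKLFKRNTQIIATTYADKVRQIDA
LPLRVVAGHAAIENSIDMRFLNDTHQMNFATLGILRVRFLALKPNPSAVVEIGYIVFRAC
HCFY
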