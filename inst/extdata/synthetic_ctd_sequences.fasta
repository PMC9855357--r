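>GluN2A_synthetic SYNTHETIC surrogate of rat GluN2A (cf. UniProt Q00959): composition-matched stand-in, not the natural sequence
TQLPPLLSSPSSNNPSTTSPLSSNGSYSQQTQNTSNSNSAATNNTPASYSTSSPLTSNNS
SSQNLSNSSASSGANTNTNQTSTYNNPLSSLTANPTQGASSNGGNSTQQATGGGSNSPTS
GSYNYPNQNGGGSNGSGSQGPNGTYPSSATTLTPTQQSLNSNSGSTTAGTGNTTAASGPS
NSPLTTPTTNQGSLSSGTTTQTNTGTGSSTGNASSSANSQPTGNYNSGTTGGNNQLSSAL
QSPYNTGSSGNQQSAATPPSSSNSGGNPPSLASNASNSSNTGASNGQATTNLGSPSTQPS
YSTGPSTGGSLPSSGSSPNPNPSSNQAGSLTSTAGTASGGGNGPLQSSTSPNSQSAQGGQ
NNSSLGNPNASGQGQSGTPQSQNGNQSQGPNLLYNNNTSSALNPSGTNTANSSNQGGSQQ
STNAGSNTSGSYQYGGAQPNNNTSPSSNALNAAPGNSPGASTNSGTSSSPSNSPSSSGPN
LTNSPANLNSNANLNQQNGTQAAASGSSGSQGLSSPNNPSQSYGSQLQSGQNSGTGNSSA
TAGGYAGSSSGAGSPYSGSTSYSTQTSTNANAASATSNAGSAASNNSTTAGAPANLNLSL
SGPGNSGATGGGTSSYSSNNNTGSPNGQSAGSSSYSSSYSPQPQPNGAPTPANASTGQGN
LSAPSSNSGGPTGNAANLGNGNALTQLPSNTNAQTGTLQGSTGSGNLYYQSTGSLSSLSG
NNNSSGAASTNSQPQGTNQSPNGPNTTQSSQYSNQTTNQNSTNSLSSNSQGYASSSGQSG
NSANGSYTSTPGSNASSSPNYLGTPLQQQGPSTNTTNNNTGSYPGPSGNGNSTSSSYNQQ
RPTAGSVNLVPNELNNNPLSVKYGAQASSRPKVSADKPLDSNSRVVDPSSLKSAKEELKT
NANTKTNRENENHTNSSTDRDYKGVLDPARPNANEFNESKGQTTPSQSDSSEKSQDLSTP
DEKRASGNDRGETALFTRSRLGLRTNNREAPANSTGQNKDRTGPQYSSSSRNANEYPGSK
KRTYHKLVAKPTKDEGRGGTQKNSADPTEGQSLGGKVHLSALAESNSSGKAAVKVGAKQA
NEHSTALPDGNYLEAGTNKDTGRPAGHGVEELNSGSAVESDEKKGPGLPKSKDPDALLPE
YNSSKTESRALASGLLNSKSKLGRAKTADNVREVGSSVSEAGSTTTADEGTDNHSAVGLE
KGGKKNPPLFPSRNTAKTQSARAQANNLGTVKGTSPPPLQAESFVSPGSEGLGGSSVKET
SADSLTADSVLGRSSEETTNLGLPYLYVQTPLNQARGVGLDSHGKKESGAVGVTVRDPNN
RKRAGVPLTEHVDGEQRRPNSTEELASADLLRLRKVSHNDALNGSRYRSKFDDRGPLGAR
KTNHGSNPNAVQELRTNSTQAADNAYPESAVEVDSTGAYYTRKYSDEGLDQRYTAKRQNG
AKAKDRPATVGGRSAGPELTTLNL
>GluN2B_synthetic SYNTHETIC surrogate of rat GluN2B (cf. UniProt Q00960): composition-matched stand-in, not the natural sequence
SNPSSSQQPSNNGSSNQLSPTANNSSSSPPSNNSGSGANQPSSSQGTSPSSSSNSLTAQS
TSGNSNSSSTSQSSTTYALSTNYTNGYNQGNSSNGLTPATQSYPSQSGTSTNPASGTNNG
NALSYALSGGGSGNSGPTPNASSATGTQSQQTSSNASSASQALNNSYNNYSGNSNSSTNT
TQSGGSTNSLNNTNQPNASGLYSNQGTSTSNPTSSSVYASGGNNSGQANGSNQSSATGGP
GTQNPSATSAPALSSNGAQGAQYASGSLPGGTTSSAASSSQSNNANPNGGQGSAPPTSYL
PQTGNSTGGATSTLTPSTSNGASYSGSNSQLSSQASQGGSAQSYSATGGTAGSLSSTAGP
SGLLTQANNSSNGTNPSGPQNPSNYQSYNQGANSSSPPQSSQSGGGSQLTTANNQSNNNN
TNNTLAPSTLQPSGSSSSTAQGPSPNSTLNTTGGNSQNNLNSPGGNSGYAATAQQTAGQN
NASSNNNAQSTSPPGSGQNSGASASLTSSSSGTQPTSAASTLGTNLGQTSSNSGTQNANT
SQTPSPSNTPLLQNSTAGASYTNTQTSSPNSTQNQNSSGTANGPPAAGNNPLPGQTGAQG
SSNYGLNSLQGPSPNSPSTSPSSGNGSSGTSYGSATLSGGSSYTAGYGSQYATGSSTTST
NGNPNSGTSSSLPSGSPGNLNGALSNPYTNSNGSPNANQNNTTGTSGGNNQSYPNSNGNA
SAQPGSASPAGGSNNQTNGPPLPNTGAGTSSTTTSSSNQSSNGNGNLYGGSNTPPSSSSP
SQLSPNQSNYNTNSTTLTQTGGGALNTGSGGNNSTYNGSNSGATSGNLPTSAQLSPSGNN
TASQTSPSLSPAEGLAGKTYKSQQKGPRLLAKNEGGDPVSADGAETESKHLRSLGKAKNV
ALGKGSGREEESATTRRYTTERRQKTAKGNRKDADEKTKEPTDTNGTNEREPAVTFDSGY
KAGAPGNKSTSDKATNSARLNPGPKKASAVVKVSQVALADQNDGDGTRSLNTGSAVNNKR
KSTTDHSLLGSDYVELGPLDDKKTEPDDGDSSPSPEKFTAPKGKKLTHFNVYVAVLSSAE
RGNEGGNSSAKTPRGDNRAVAGVLSHTGLQAVQTSKSLESNLSDTSSRQKLEENNGHRET
RSLNEDRKEALVKPDVPSNGSNELYKSAPKQSNGSAESGANENAPTKRVFLHLNDVVSTP
AARESANGNASASLSTLGRRNGNPLSSLGQQRKDAGQYTLTANASYNSNYAAPFSTPRTG
LDTLLVDRHPSGLYATTTANRPLGESRKAGLSKTQVAGSSSTSLRAGVASVTPETNSELG
PQELGTGPFNADRELAPSKSQNAKNRKRFFLATRKAKSLNSASASGLNSEKEHGKNTFTL
VDYVGSAKQSPGTNLVETGAPSHFNGLNDRALAQSTKGNATSLNVGKQPGVKLVLAGDDE
NASPPSKFLSVARSHDKQNSNAEGTGRNNDENSDGGALSLTT
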