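>ref_pylB_synthetic
MRPYTDVRTHSTDLSGSLMEDMLNVVIAAITLRFPGISGAGVFYYAEHTGFDNEKIVLVR
VPYLPGRLEHLNGRDGGNLGISGASFPKGLKIRAEIDSIRLLADLKQRVGTGVFGAGAGW
GRFLPEQAPLGPRSETDNDEPIDETPLGLASITQPAGEGTKKAVVRGNSYLGIAGLVPYM
SWIAMTKFQASRNLDLDILQEQEYFILFYKLYDRLPSTKDRLEYYAIEVSADGKEQWPGK
QMVKLGIALDSVETQLKAVFAAERSGFVDELLSDSSITASIELPADEWTVGQTTHKVVLN
VFNKSGDTEDGLMVVLIRGLMLQTGQYFLEHEGAHLSTTLYPGENQELIV
>ref_pylC_synthetic
MGRRLSEFFMDQQVLTNASLKSVWTDDFDYIETPLTKYGKNPTGEVQCVLNIKEPNINIG
QMLKRTALLQAQYNGNRGGPAVVIKAAEIYNPLGFISANLQILDVSFSAVISYSMVFQDE
GILAWLLALFSQTDIVAAQDIEDQARGVIRLGLKIFETLQHAHLTDQETEIGKHWMGIKL
AYREKLAVGHSHGLVPPGICAFGWTVQFPRTIPTEKIEDQHPGSTKVIDQEDGNDFIKRN
SATDQIKELLIPSGTEKILPVREMFVVGSPLRADFFETARPGASIHGQQNKIGDDGTEGR
DLGGVVVLREGCNNSNPFVEWAYHEILILMPFSDTLILPQAAKRAPINSRIDLVEWMLRD
LRLDGSNMGSRSDLGIYEME
>ref_pylD_synthetic
METTQTLMAMVVSYTISVGAILFLDYRGLVRIIRDLQLRKFGLAGNAEQQRHLTEILLIL
LAAEAKLDIRIPVANGTVFRLEDDSGYTQFPKTGLQEESFDPEVYFHYTISNSGFNCLID
DYVRHLVNFDHDLRIVSKRNNTINILDKNPESSKSEILHQHCKFKMGEVYAGDFWFDLIF
TYRMNDFAYAQTRAIIASPSVDVSGGPGWNEADEKFILAIRVRQLETLPQDVVTLFERQE
MLRAPRLLLP
>ref_pylS_N_synthetic
MNAENTAPSGYMREFGHGMIKFPLLKIYWQLGDVDLAARVSNALETLENDAQPDAALELR
VRMLRERCGKCNVREQDMRWADRSTQSEPHVADIGETTLNSKLGAAPVAA
>ref_pylS_C_synthetic
MDANEYGVRYRSIGLYQGRLGDVGLKKDGMGLHVKFLAIEDERVGLEWASVTERQIYVEF
PAKLFVAEMNGERIANRRILNSVYRVYSPDERGSISVAQITAMLIQSKLGAPGKNDSRRF
NVLPPLHEGDTDDKPPSDTLSVQAALLTEQAEDLSNRRGDGNLAISAAMRGWDPLNIGSF
ILRTPRPWVHRVKALAFLWMRFVSGTPVANVAGTPVLCLGVMTNDGSQGDTIWYRWEIGY
AVDILFIHFIVSGTDRETAHPAIVDWALLDASIMFQEPRA
>ref_mttB_synthetic
MKPQYSDVFPKVPTMDTPILVILNKKANHSIFSSTLVRTTGATPVMTGGPRMEGVAAQKE
STLEEASQYRDSCNMCAMHLPSRASCGATAVFRAPYMLTGLILGKVAANEDAKRQANEIT
LDSGKHMTIWSLLLEADLLDVEFGIILFLAISYLAVMLSGGTSVNATGNLFQAAILGAGG
ACALVQELRLIDAQLVAAVAOTSADDPENRSFMLAKVQGRKVNHFPTYDNTYQSLVAGVL
TLFKLSGQEAKSVGAVTLRLFARKPSPLINPIEPKLPKGPTREIYLGAFWMSVVLDVKPD
VEYSKVDIAQYSNLATAELVDGVQSTRPGKIEVVDYEKYLLDLFARDGKFIVPGKIKLIE
GPVIALDPPPSQESGDGEAAGALQVEAHVGKTFITLDLVGSSVAPAEIRTARVAATSTLI
VNGKEVNRRGIREGISVAGEFTARMLATKT
>ref_ramA_synthetic
MAKKSGGHGNCVFADEYYKVNSSKKLLLDPSFKVVMRHGNDVVRAEELFTDASQGADVLN
SAMYFAKSVGLDVSVFRHTSESLDAGYQPGRDAFHILYKINTRAHRGGGVCKANLYVWGF
MDGRVDDKELIAMAQVQKTAFSAANYDDRTDRSYRIQHRNFPKFAIHNSPVFVKVVFLTQ
DAVENTVLWAKGAIPDVGTITYKGVRAKVAQNQSFYTPESGAIPECILWEFLGENINLAT
LVGVKEGSLLGDSYSHELQDKGGIVAHLAQEAEPITGFLPQQNEKALRPARAMVLDKMIY
NFSGQIRKERDLGKLTYSVLVFLDDHQRLLVVEDWPIMLGVGIQRSLGHDLNTPRFYTAI
LETAPVDSIETRLEPHLEQNGEMGEFIVGMEQDSAAEFYKGPGELPSETENATATVFETI
ELDDYPLHIGSMVVKVGVLYVVAMIIFVPC
>ref_mttC_synthetic
MHELEAGKNLAGVSYLRQPERDMTGTKNLNVDKSASRQPSLTEVGLVEQRMARWVLIVLI
LNAKSMGGGMGVATVKFQRTEVFGQNCLPDAMRAPQLEIGIEKRLMVGKHMGADLSVSTY
FVRNGDGDMREPYQLQVDTRCNDQPQDSLLIRALAEYEHLRIATHRDILAKRLKMYNWDM
QEQLPALDALMGLLGDPVPAKNESAPSAADTADIYAVESE
>ref_cutC_synthetic
MVFCDIVFGPFHVEHITLAEEVAEESDEQDYAYGIIENLVVLFGTHEKFVIQGFGTFAGI
QYRVHAFRKDKREARKNTVGGRQKRLHLGTKSGQCFTLALETAVSYVDKYYQERQFNDAI
HMGNAHGEGPNTFWQGVEDWTSQIFRARIVAVEFYMPAAVGLRGKPKVFEEETSTFGKFL
FHSENCVVRAKKGPEEGFDVSQSGWLKSELEGALTGGKAYTSWKIVAPGVVVRFKADTGG
PTMSFFAVGVLGWVAHRPADRFAPLDQRPQWTVFLNFVKPIVEWKSTVGIPTKLDLDGQM
ALWKSWQYESPVDFLISGLNFRGQRPNRVSTYDDRQMRIAPDDNPNSELKWKELLHMAYL
LANKDRIGERRVEEQARNGNIGDIVIHDTQGPQSEEGTMPNRGAAQLIMVRLTPNRYILR
TVEAGKAKVSTTIVLGAGPRKGDLVMPKNSGLSALKVLNRPQAPPIIEELSLSEDLLRDE
SGVRFAEADPVAAWSQIRSE
>ref_cutD_synthetic
MNYSLEIARMGKLMRDRAICCVNSRHKRSKMHLWFDLKIHALNAGHFEEAEALEDIARVM
LASDQKVFTFGVPSAALSGQDLIGSHDLFQTGFQIVADAGRGCQHLDDETFNSGPAQYRY
ASDWSSIVTQVVQAKYSSDVLQSAAGDQAEDTARVEPLSTIFAVKPNLNASGRLTGIIVM
YSIGVSPQIVGWEATGQRIGILIIADQAVEATPVDIDARVYDLIRPDTAEYYDEELSKLE
ATRIAVSTKMLLAVRKTEWTVAVVLVATLGRHQNPMSTGRSLHLASFSLPLQRENGATKS
>ref_grdA_like_synthetic
MRPQLVVNFAVLVTKASSVVDDICLGVCSELPARTSLVEQGAEADDAQLIEIAHRGAAPS
LEAILSFPQAVRRKNLATTFUHVTRFRHAFAVVGVQAGEEPLVEDAKLAMRAYVLSNELV
LILQAADQNSLSTSASIPMIDNQIVPFGYLHPLNDKPTKS
>ref_selA_synthetic
MLLGILNGAGLLAWEFAQERKNRAYLLAQREGDVVHLGEGPSGLDDYIVQKTVDNNKHLY
GMILVTTGEKSLQEDLERCPGDGDNTESTAVILWPIFVFFLSLEFYYQEPQAVSRVIAAP
IYLLAQPKLLQVGRPRLANVLLIEEIGDTGTGSPDTTSVIYVHLRPNGPTLKPLLRQLDA
DCVGETVAETEILQHAADIGIAEDNYGYEAHPAKLLASGKDCSLMAAYMSLMLDSTAPGR
FMPGHAEIMVISSPIQTDAVLGVNLIRDAKEGFPRELNNLAPIARVLIQGLTGTVPERLN
GKPVAATDSLEAEKHMQSLDTVEIVSVGLATIGDFAMMINVYVGILFRASHALNRGALAD
KAIFANSESTQWECESETLLVCTLHKLNTQFKPEAAGELL
>ref_selB_synthetic
MYQATGGVLEDLKPQEPSHEARQKTGFGVGGSVDAAFTLILLLAETHEIDLGIARELGRT
LCFPLPAADAEKIMEACALGEGNGMDQALRMTCRTGRQEKLALVRAMVTIQSTKAYGDDQ
NESLENKELVSGNMEGRGFPNVSIRGRDQTYLHIDIDAIQLTFPMLTTVTSLIIPIVTWI
DIDGYSGFEHLPYMGTDRKIIPLSMRLVIWESDFYASIGSQNLIHVFDNQQLIQQTEQQL
QLDLYVLIAFKLQIGDRVFNFVENGVLEAPTEKVIGGIFISNLDMIGKAVPEHDAETQLP
YWLLISNGQIVELVILLIRLKNAQASYGANILEFARTMCRKHLANEVIMLALGTMGAAHG
PAGPLKLDRATVGALDQACHGLSGTLVRDSSQFLLVAELR
>ref_selD_synthetic
MPHSVTIGRFMRDFTVAEGSKRMTDTMGLIIASTNPTCGELEVAKRIRSRNPPVETIATI
VLDFFVLRLRDQTIFAHVPTYGKQYEFGLVGEAMAADPNEMPGLPSITVTYNYEDLRIVL
SVAVGKTYAVRERVEPMVSFFAFHEGRWFAWTSVLCAHGFTFFTLTGPLITPVGRFVRVL
LLAVSMRGASTRSYESRVIQTWLVVVGMQINKAMMLSRPEFSTCLKWISEARGQPFLITF
FTQGEYDSQVGKEMTMRSRELRVYMIQRGVEVMTEMCNKHIPMYLDMESDFGDMITPELA
CSTVIGVIVMKNALATFILSENFRFTVQQMAGDFASEKLF
>ref_bcct_synthetic
MNLMSLKDEFMVLAQTDVFGDDAVVNVALIAFEQSEGEAKSKSGSHRQASHLEEVLGLRL
RWQEKTAFNIGIPSLAFANDWFVNLLLQAELHFPSCSAQALGTVLLFNAVNDAGGTTITI
NGADTLFDLFPSAWVEVQGTGKAAHAALPDGRVFADRLLDVQRTISRTQSRGLQILELSG
DEAEFYKVLVHLYTIWHEMSNVISVVGDVLKKDPGAVIFEGDQSNAVPVIKREEAIKHLA
QGTLDTMANLCEDFEREALICALQINVRPSYGITGGDAFTISDLVLDISNVAFSGVSPRI
NAVKIQTGANQTLIRFMSDALAEQNGDSATLYHGGMVKPKGSVATTLPADISLLMGDKAN
QLAGYAVVVDLAYVVQINRIPSVEMIGLPEAFTILPLSMVMPRWNAIINLPYVAPETLPG
ALAPYWPTRSTLQELAYKRASQIMDAGEFGIDAICSTREPAPAGLRPISRSNDALFTWVT
>ref_mtbB_synthetic
MGLANLSENSTVASREDLRLPQEDQTMAKRATLTAQQQRGAPAITRLKEMLFAVRPSKVR
QSLTQHLNQTGGNWRAGHVSASDDALLPDAADLFYSQYETYIKSGEEVEIEGSIAIRPRE
DQIHVKIPILIARAVQERIITIKALELIKMNISTQQNEQVFFSNFASGVEWAHPTFALQD
QEAVMGCQMATSTQPVFVATGYPARKADGKNDSSVGYLQKLADMKVYGPLARSESCEFLG
QHRIVQLRSLTPMENVDNYLAEYKYTGSNTKRFVIISVEPKLIEQIMPIRFVFRLWPFGP
LVSMEKGVHSNESSERPFAQRRRHKAPFLNRRTLIWVLIRVFAEGSKALWDNKGAFQGIL
VLILRKFEYAGWTELSISLFYEVRVSNTLFSPDLALFGRQLIPGVRTLPMELYVKQICNG
FIFMNYTYNESYNEYTCHKYATMTHPALSEAGICDPCNPR
>ref_mtmB_like_synthetic
MARVFAGLKEVCWGNNYMYTSKPKQTHLEGGVVAGNWKDMYRIFQNKRLIMVRAWANCQI
KTKCLKGRLYTATTEVRLGIYVNSSFQSGCFDKAEQLEGVVRGYFQLLDLVAVLTDAKLQ
TALSQATLYGSITTNVVDRLRVRRRGKGDYFWFITVLVAELDIRLQVSLQTDLLEGYRSG
DGREGIHEVKWTQSSRDYDKVRTEARIKILPMKKPKKEGELNYAFENEERVDFWEELDHI
NAHQVENTYALADAADRLGALDPMEWIGSTGSDILPRNLYLNEQNKGSGVDVILSAVPAL
NTTGRALESLDFVYPLFRGELAEADLRVGVDESQAIQPTQEEKMWDSATVDFLLIRIEME
QDIGILLADAEVDLINDLAELITRLTQTLQQHSNNAIYPSLLAVIQATLKDGLTPHENVQ
SLLFMYDTVTLAWMMKEELRCTVYIPYGEGELLLWVSGLP
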