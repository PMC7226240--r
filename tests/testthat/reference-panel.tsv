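id	sequence	gravy	pi	instability	aliphatic
ref01	KEWEGQTDRPQCEEFFWAIGPGASIASYRRSIIKYQWNKICGETFEKPWTGRVLDYNDVFTAKLKFTFGLQVKTCNQRRCYLMRGILPQRRCTDWALIPFEMNFNMAHMQNRPNDSDPC	-0.664706	8.814327	34.767227	54.957983
ref02	AWMRGTVTWWAWQWIRSIKYDSLMWYLLWMWWKQMFRGEWLTCDNAVHWTQFDLHADNSEMEYSRNSLISPMELRMYYIWTIGPWPVRECSFMEKKLFSMPVAGGAPEGVAPSYPPDSTPCDVHQFGYVMWRNWFQWCMLSFEFKTVQWNDIWMVSGYLYESYYWVLHYMSWSGKYRHSHMPAPFPEMMRKDGRHKAYFRFHWMYVNLWWRRGGPAFYDDHRNNQMMRQWCRVGSKKHVDIPTQKEKMRARTCVTKHFQLQDGGDNWFKVSFWEERDLLAERCCNSMEYFA	-0.588660	8.691192	45.597629	48.900344
ref03	SAQSVNIDWFNEMFVATNWMWHYNLQATDERPYTEMITGHWGCQRLFSSRSHLTMMDPIQSKPFPPMYGTTCPTCFEIYKDDCWGEASHPHYCEAARQMAEYHAWDIDKGCEG	-0.636283	4.986280	51.713274	39.823009
ref04	CHEDKIMMCMLRGIPQQMGKIEIFFMPLYPMPVYVLPRPTMMFNSVCDFTQWVETFCAPWRTRKKGDTWCCAVDVTMFYIVHYETDSFDLKPFGRSRSDTHSPRRRYEPIWLGMSVFTHTYPVCSHETNKGQLYKRNDWIWIGTGHPNCCAHVSVRKQSNWHGQLEFDCWYGFMGHMYEKRTNMAWLCYPLWKKGSWLNFSNHKLIPISISEVCQQYCGEEMPQWDDDSRGAHRFYWDTECAKKSELCNRWVV	-0.496838	8.157717	54.907984	53.873518
ref05	HTPYSVNHLGEIKDFEQARPCHCRMYIVFIRPGEDEFGNGYHRQNDRIFNGALPYIEWHDRCRFWHRPFDANRYHPEMQTWNMDPGVCNCCCKRSWRYDDADIDWLGPWCEWLLKKRKMWNSVHNNTHRVIPSMKNMCSGFYIPATRGDHFFILAYICWSEIHRTTLEVSCGILCMCHSCAWIDAGAIKEVSHPTSSMQTNFGMQPEWFGNRNDLAITDRACTPTNGNAEFVEFASPGSEHSKFVVPQSIFWMKSWHFIGEHMNSMMQI	-0.500000	6.609829	40.740558	54.758364
ref06	QPKCCFPNLGMIKMDCQEWGDGVAQVMCYVFTHTPRMTHYCHSKKEQTIEGFVKMTTEPCMPHFWCWSDMAFPQFRFSETFMGQ	-0.353571	6.436584	55.807143	30.119048
ref07	DCHVCEPKKLQGAPNRGEYFKMGDNNVLCQTIIKGWGIKEAVECEYKSCYFVAAWHQAKLHSNRHALQGLNHTQLTKHPEPQEEPFRASTCDYNAMSIWRLQCKTPRHGFEECVQSDTAWVPISWACAMGQCGQAQGGAIIRIQMVTLDIQDASMVQENMPHEYMLVWPWPSNPMPRVFSDHETQKQPMCGEFEAKHMDSASHVPTCIKWGKQLIAWMTIDVPKGEPFNWYGFEADDGHSPTQHNELSFDE	-0.589641	5.687617	44.507968	56.772908
ref08	DSVQTTSDCCTACHWANATAPLHFQSLKRKEAEGNYARIGADDMYNRRATYMFCYKEACTCRWTHTCQKSATAWGLDKSCQYCWTDRLSRVLIFRRVPKTIIVYNNVHALCHIKFLNKYVVFLMDFSELARWNQNHNWTVWLILWPCILMRLRWGSWHVSCVSYKWQEAIETPEGQNIWEHKTHRLLGPINITLGFNASGVPWKPWAMMLELLQCRTVLQKKLGRRCTRMTGVGEMSPTFVLFPGDLQKVTWDWSALVRFGKQVMSLMQ	-0.222677	9.288556	57.559480	76.840149
ref09	MHGWPENIQHPTQYHPKEPFNSNSMPVTLAQTIMVSMPIALEWPVKEGIERRWYPGKWVNTRYDIEGAGDQLGWT	-0.717333	5.817948	68.049333	61.066667
ref10	RGNWVAVNEVVYMNEEFHWRSMAPSIWCWHTFHWMPNYFESVETIMHQMKRLVGLEFIYGQSGPFANGALVSLWQRYQIIWFKSIHHSKPMGIVLQFPCFVRMNVKEEFVGHIVGPFWLSSDPDWLWIHGSYLEYCCMGFWPTQGDITIDARQSTNGFRRMNISLYNCISNGADFGGFDYMYMANWDIKSFDNVNFMWFSLYWYFWLNDHRPTWFCLEMGDSYCVSQ	-0.127753	5.800328	46.165198	65.638767
ref11	MAHCHCYAVRYCQAENQSVCMNMGNVKTWKNSACAEGWLLYAFPKFKVVSSFCGNNIFMKWPANLQLNSPRKACEGAYQHFPDYPAQKI	-0.298876	8.905550	52.423596	53.820225
ref12	KWIPKDKFDYCTMMWPECMTAQVNVIKTITYTMAFTHHLQRVDEQARRWFFYTVSEHDHIHN	-0.561290	7.134112	70.601774	55.000000
ref13	LCQTQEQQVCHVGNWCRDNPKRLSILRNDYFPGPWDHKGWASKRNEHDYDRFGCDWFTYRAEKFWSPGMRFDLDPKLPFFCQNRDQTQCAQDIDPTGFDGDHRMNDPHFVRDRCEIAAMRFQHTHNDVELHLCIYVHFLTCNVPGQDDSALHFQERVEHHFVSIPNSGQKHIEGWCANSESCFKHFSQDWVGPCMLRENCTFMYMCIKDDWLMPDPGHWIVKIELRSMMHCCLGVIWQVENFWCHDGPC	-0.645382	5.810900	44.207229	52.811245
ref14	MKCSRDWLPNIRVMEVAVPPIQNSEVYICHGTFRVHFWSQFFKVYFWSTYNFIPRDQFTALQQKYLQKPHTYCIYWAHDWCGYAPPEQNWGAIPPACTMYEKWWEDRPQMSFDRSCLMPSTNLTEIHWIMPMYIKTCHDNGGMNSMRTMQSVMSPRLAQRYIYFNNCGYGMSGIWKDAQRPPVIWGTFADCLRRRNAWGSYFEEGQFRWWWCYVVRRRVAFRINHDKRWLNCIAW	-0.481702	9.134735	65.642553	55.191489
ref15	HAMYSIGMGWCFIKARNQIPNRQQSCAKGTFVTLEANLYQQRNQANHIYKVMMVFMAAYHPIINMSNEFGMRGMELTHMGIHMYLAITWIPCLLDCKYMHMARDGIIKRRECTVVVRYDIA	-0.021488	9.249102	54.396694	80.661157
ref16	NTYWSTSRVEWKKVNGLQMIGALAVIVSQECCDHNQEIRESAAPLYVVRTACACCPDPFMFHEYCHLCPCRQTYNIQPRVQLQLLTEQHSGRWEGSDKMYPCAFFQAADLSFETRDPQITDDRWKSMNGIEESDQDHIELCKNPLYGGERFNDLHSDMWHRCTAATDYCWGICTTCWKEWEVHHADPCNKICEKAKWLDRHKTPNRAAQLCMFMWTTETHIAPLRVGRYGTWRCHCDTGRCDVPENWNLSCVAETHHFFEQE	-0.619084	5.763212	55.180916	55.877863
ref17	QLHQLIFHRGKRDWPSRFMCCLDWRTCFGDVCSFQYHCQLDGYPLERWTNQEGQVHMHCAVEDGDDMCMWDHEHWFYRGRIWCGVECRKEEY	-0.783696	5.725528	41.235978	43.369565
ref18	YIDDPRWEGIEQHCTYQETQGARDETDHMWHSMKPRAEHMREWYNVECIFKFQPAELDSCQQTRNVQPK	-1.337681	5.196585	50.634783	35.362319
ref19	AKMNEKDLKTCQVPRGVYKDTARERQVTMVITPKTIQEMTGKFKTSFTADTNVTANPKDKVNQQNWIHSLDKSGHTGRSKWCGFFHYWSKHVQASSRNKFPCFYWYWHELCHADDWLKCMYYPYENAAFNY	-0.871756	9.193659	25.210000	42.442748
ref20	KIGKSMAFEGRCYTGWVRRGRAQCKQIARKPYNYRACEKGSCRIDFGNNFRMHYRMHWFATIKGNLTQP	-0.871014	10.361053	36.611594	39.710145
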