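>seed_orc_cdc6_01 synthetic Orc/Cdc6-like seed
DTDGFTMGLNFEGEYPGKTLFDTIQGMGVYNNGDTEIGGCKGKTGDSELGKTEHYHTLTANWRAKITHRTNCDMSPMIPYKFSVQMLEMIRSVADVYYVLRNGSNGMCDVNSNKRAVDIMHVLHSSEKDGVSVPCVDESTDKIGSATFNDDNGEASLMETAEKMVVGAFDDFHNGGSEHCGMDTEDHDMYGGIHFVALSRAIMLVISSGSLGNTGKRNHLAESDRARKNYYQADVLCVAGEEEYHYDETMQCDLSVKSGRHQGAMQNGGIANVPDLYAYRHVVTRSDVAIDIEKASAGVVPWLVASRTSNDWAGQFVHNERMTVSVLTVDELTEHSELMEKEQARHKALMQELQARWYDDNYPNGLYVPDWVELFTCYEVYPIEPTTSPGEIYCDQV
>seed_orc_cdc6_02 synthetic Orc/Cdc6-like seed
HNAGMPHDSNLADEIFVTRKEWLSEDDKYLPGHSRVGTRAIISIAKEHLEEGGHNWRGIELDLGDSELGKTIDDDEIQNVDFRQVMSSLNRVGNTDERGEDEVELPVDHNFVVEEKGISMTTVDMNRLKCLGELRYEILLPQKGDALEDDIKPNDLPQDASVDDPGEWRQSIAETCDQHDSGGHDVILAVEHGHWNIDDETLQHDREEDKQQDQDWMRYDAAPKNGNDKSHNTSSSLQAHLWGDYQVYAGQAMTFSDGEKEDLYDRLSWKGNPGDGDELDTSHTDHVNREDGDWTSVHNALWPGADSAPEAPMFSAFSQGDKAFIQPESVDPDAKRELAELLQARKEALMQLLRARGFRKTTYITYRHPDVRYMMLFVFTAQALGKTDNQLAVMMMN
>seed_orc_cdc6_03 synthetic Orc/Cdc6-like seed
YLEQDAIGNLQNTIVVILHHVLLDSDYLRGEKDHCDGAFPEEKPGVFRPGDSELGKTGELYKQRYDVEANARFLEDADVETEVDGNPYLMQDDKPRQGGAKEECMHGGLDQANYHKRDIYKDFHDVDEEVEGENLADMRDHLGEHRAYHPTMPGASCSDENIEGNDYAPMTGAKCMDMIVMIWEEVKEVMPEEVVTYGVIQRWVDVEVVDYFNSLDIMFREWFFVMAHALSESGIKMADELLLHFDAYLHESDEDEATGLERRECKEVVSNREPESVMILIDKEYAVNLDSMHDLDADAEELRRPQDNQMENEGTNEEGELAERLQAHKQALMEELQARALQGAAPYEFKTRPAYAFCHSVFQDDTLGEERTGHILKDEQ
>seed_orc_cdc6_04 synthetic Orc/Cdc6-like seed
PRFHTDHVDDMVGIYILSKLVMYPATEPNNRFENGWVFTKDWGEDSKAYANKTTIPFVGQLDTEKKKYMDYIRGDSELGKTSNANWGTALVMRIASDVVVGELRHRSTQRYHVILHEGEMRKPENEEAMIVRMMNMAEANLVDFDRETDDGFFEMMLSQEMSTITTKPTKLDDNHEMYRESPDVEHAWRMSKMTDPMVYKLQEGVNKSFPDLIDHVFCPSHNVASLEEVYFEAVDLLTPEDHIVDGQFGTAQVANDMERLNDAVAQQVKFMYHQEAYFFHTETYAMQHSRQFVMVVPQWEPIHELDDDDKEVNENMAQEVDNLAEEQQERMQHRKEALMLELHARDSTILMERQVGSSGDSTPRGRDNNDTCKHGHIPGSPSSNAQ
>seed_orc_cdc6_05 synthetic Orc/Cdc6-like seed
YEEWAVGRMDMHNPHAGEAVVDHLVLMAYVSDTMMKERTIYLFDHDNMVESLPTFAENGAIKGTCLMGDSELGKTEKVAVEGNDDMPVSHMDMEPLLEVLFGKGGTPIELEYDLTFKHPIVYWAINGTSYLNKWEPRWNVDAAEYNAIQIIDLEMSHSDEMDMHGALQGDAVYTLRLYSNDVVGSSNAEKSLDPIVEYIFTDVEAIKRFHLNFMSGKDSDVLLWVQGQDQQENFAATYGFEDKLDNTMDPFRETGSIWYMCEKSDVAHIGAKKDEKEDVKMAAPMDKDGDTETNTMIEGDNAVKEDMGNMHKNVVYYHNDIDLALPAFRQQGFLIRGFDGLKCMKLLLAERLQERKEALQQEHMARDSMLEIFFNDLTWYGVDILPSEPEDAHSEANQNSDMASVTL
>seed_orc_cdc6_06 synthetic Orc/Cdc6-like seed
AGLWGRMDAFCFDDIPESEQWSFCNHQSATLEIARREVAYVVGFTEGHSEDEVEGDSELGKTNYTPGRYANDEDNHANNDFRDNNEKIHGIEEDPRAQKCKGGYGGINSTKKADKLHELPGSQDLDSPYDDFQVHLPNYDFLFFAGEYYFGHDQYLDLASMWEQTFDNRSEYQYGTDSGNTDSDQNERKIIHGIIGHLEKCRDKDGAYHVLVGEDLEDYVCMIQSGRLRNDSTDKRRAERMSDHTAFDMRVNFEDQEVALMCVNRTAGRDMDLTFDDEIMEFDDCVNDNVFKQKMAEGIQCEAAAHHQAREQDIHKATKAHLAERAQAQKEMLMQELHQRNFLRVQIETDAFPNDNEVDGAEDTDYDEGVTHYTMQVWLSD
>seed_orc_cdc6_07 synthetic Orc/Cdc6-like seed
FEGWPHKPTRMLSAQLAYPFPTSFEGTPGFTECDQNGFGVAPRRGDSELGKTNRGEEEASVGWDRASMQMLSLYAMDNAENEADGEDKLPRKAAACGNIGHAVELFAPNMDEGFPDRLDTKYLPGPLFNIKFTSGKSVIELLLLATLLEEGYAFEREFFANQRNHRDHWTTDPLAVSELEDWDFRGDFDTHGERNEIATQHDHNYTRARDYLQLDPLVPGISQLDMRMINREAHVDCHCGTRGLLPPGSAEEVAECNRNTPFDFIYFVEKEPEKPLMGRADNQPHDNAVAFFDWDGQHQMAGMTDATFLDHTHWEQDVLMFVGRIDWVEMDVFTRGDPLHHIKIKVLELAERLAKRKEALMQMRHHRAIDRGGTSYNDGWALAKSEATIQGKDKWGLPTAQLARARGV
>seed_orc_cdc6_08 synthetic Orc/Cdc6-like seed
NNEQEERESIEIETDEDSGDSPENLESVTESCMALMCDYAPLISNEMIGGGDSELGKTGQFLRGVRAVNELKHIYTGYERHEQSDMKEQFPDNLTKHPAQHHNRDDLVDCAMDHDEYETAMKEELLTGVNYGEFSRTHEETMKTHREDDCLMPEDHEHGEPINTMQIPDKTWVMWRPWEFYYDNLYADLVRVELDTWAFVGPMHLSAQHEQIMRFEFPVITITTDPKIAQTRGKDHAEHNPPHMQVFDFRNAAGISWGSAKVMANGMQEHEFEKDHLWQYRYMTLVPNTMDDQMSIGSIPAYRGAFRVDLDNHSDDSPYSCAVILETEQKQRLQARKEALMQALHALGDVVQDINILFLDPNMIVVKWVFQGEAFSAGLLYEEHNLES
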