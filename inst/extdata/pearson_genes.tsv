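1367624_at	NM_024403	Atf4
1367648_at	NM_013122	Igfbp2
1367654_at	NM_031819	Fat1
1367660_at	NM_024162	Fabp2
1368170_at	NM_024371	Slc6a1
1368559_at	NM_017091	Pcsk1
1370030_at	NM_017305	Gclm
1370240_x_at	AI179404	Hba1
1370442_at	U25684	Tmsbl1
1370575_a_at	D50734	Azin1
1371433_at	BM384999	EST
1372754_at	BG666424	Appl2
1373092_at	BE109587	Tgfbr3
1373260_at	AI412606	Caprin2
1373380_at	AI169085	EST
1373699_at	BM391164	EST
1373870_at	BE110630	Fam98a
1374004_at	BM387902	Prepl
1374709_at	AI406795	Hlf
1374812_at	AA818197	Ptpn13
1374941_at	BF397951	EST
1375856_at	AI102258	EST
1375964_at	BF282282	Psph
1376836_at	BF419655	EST
1387037_at	AF022247	Cubn
1388145_at	BM390128	Tnxa-psq
1388608_x_at	AI577319	Hba1
1388770_at	BI275670	Ufm1
1388795_at	AI101500	EST
1389020_at	BM389149	EST
1389135_at	AW140637	Ctps2
1398348_at	AA945604	EST
1377725_at	AI575322	EST
1378320_at	BG373845	Rlbp1
1379566_at	AW527929	Rbm11
1379900_at	AI043697	Aldh5a1
1382008_at	AI044348	Rnls
1382021_at	AA850650	Pkd2
1382905_at	AI102514	Mrc2
1383413_at	AW531481	Hhat1
1391923_at	BG376838	EST
1392108_at	BF390648	RM2
1393165_at	BG377684	Tmem206
1393373_at	BI289640	Opn3
1393837_at	AI145227	EST
1394029_at	BF283049	Vma21
1398616_at	AI045228	Ap1s2
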