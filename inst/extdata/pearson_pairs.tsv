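1367624_at	NM_024403	1374941_at	BF397951
1374941_at	BF397951	1367624_at	NM_024403
1391923_at	BG376838	1373260_at	AI412606
1398616_at	AI045228	1373260_at	AI412606
1370575_a_at	D50734	1373260_at	AI412606
1389135_at	AW140637	1373260_at	AI412606
1382008_at	AI044348	1388770_at	BI275670
1383413_at	AW531481	1377725_at	AI575322
1388770_at	BI275670	1382008_at	AI044348
1370575_a_at	D50734	1393165_at	BG377684
1393837_at	AI145227	1393373_at	BI289640
1373260_at	AI412606	1391923_at	BG376838
1379566_at	AW527929	1391923_at	BG376838
1373380_at	AI169085	1391923_at	BG376838
1370575_a_at	D50734	1391923_at	BG376838
1377725_at	AI575322	1383413_at	AW531481
1382021_at	AA850650	1367654_at	NM_031819
1372754_at	BG666424	1367654_at	NM_031819
1393373_at	BI289640	1393837_at	AI145227
1367660_at	NM_024162	1373870_at	BE110630
1367660_at	NM_024162	1370442_at	U25684
1376836_at	BF419655	1375964_at	BF282282
1394029_at	BF283049	1370030_at	NM_017305
1398348_at	AA945604	1392108_at	BF390648
1374709_at	AI406795	1389020_at	BM389149
1387037_at	AF022247	1374812_at	AA818197
1373092_at	BE109587	1374812_at	AA818197
1370030_at	NM_017305	1394029_at	BF283049
1374812_at	AA818197	1387037_at	AF022247
1373870_at	BE110630	1367660_at	NM_024162
1370442_at	U25684	1367660_at	NM_024162
1391923_at	BG376838	1379566_at	AW527929
1375856_at	AI102258	1368170_at	NM_024371
1368559_at	NM_017091	1374004_at	BM387902
1391923_at	BG376838	1373380_at	AI169085
1374709_at	AI406795	1382905_at	AI102514
1371433_at	BM384999	1382905_at	AI102514
1374004_at	BM387902	1368559_at	NM_017091
1373260_at	AI412606	1398616_at	AI045228
1375964_at	BF282282	1376836_at	BF419655
1388145_at	BM390128	1367648_at	NM_013122
1373699_at	BM391164	1367648_at	NM_013122
1389020_at	BM389149	1374709_at	AI406795
1382905_at	AI102514	1374709_at	AI406795
1373092_at	BE109587	1374709_at	AI406795
1367648_at	NM_013122	1388145_at	BM390128
1373260_at	AI412606	1370575_a_at	D50734
1393165_at	BG377684	1370575_a_at	D50734
1391923_at	BG376838	1370575_a_at	D50734
1392108_at	BF390648	1398348_at	AA945604
1367648_at	NM_013122	1373699_at	BM391164
1382905_at	AI102514	1371433_at	BM384999
1375856_at	AI102258	1379900_at	AI043697
1368170_at	NM_024371	1375856_at	AI102258
1379900_at	AI043697	1375856_at	AI102258
1373260_at	AI412606	1389135_at	AW140637
1374812_at	AA818197	1373092_at	BE109587
1374709_at	AI406795	1373092_at	BE109587
1367654_at	NM_031819	1382021_at	AA850650
1367654_at	NM_031819	1372754_at	BG666424
1388795_at	AI101500	1378320_at	BG373845
1388608_x_at	AI577319	1370240_x_at	AI179404
1370240_x_at	AI179404	1388608_x_at	AI577319
1378320_at	BG373845	1388795_at	AI101500
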