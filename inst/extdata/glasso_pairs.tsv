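1383294_at	BF412731	1367624_at	NM_024403
1373260_at	AI412606	1367624_at	NM_024403
1386911_at	NM_012505	1367624_at	NM_024403
1370240_x_at	AI179404	1367624_at	NM_024403
1373260_at	AI412606	1371352_at	BM391736
1370240_x_at	AI179404	1371352_at	BM391736
1367624_at	NM_024403	1383294_at	BF412731
1373260_at	AI412606	1383294_at	BF412731
1372002_at	AI411352	1383294_at	BF412731
1398616_at	AI045228	1383294_at	BF412731
1367648_at	NM_013122	1383294_at	BF412731
1371245_a_at	BI287300	1383294_at	BF412731
1386911_at	NM_012505	1383294_at	BF412731
1370240_x_at	AI179404	1383294_at	BF412731
1388608_x_at	AI577319	1383294_at	BF412731
1373260_at	AI412606	1367590_at	NM_053439
1386911_at	NM_012505	1367590_at	NM_053439
1373260_at	AI412606	1368145_at	NM_013002
1386911_at	NM_012505	1368145_at	NM_013002
1370240_x_at	AI179404	1368145_at	NM_013002
1367624_at	NM_024403	1373260_at	AI412606
1371352_at	BM391736	1373260_at	AI412606
1383294_at	BF412731	1373260_at	AI412606
1367590_at	NM_053439	1373260_at	AI412606
1368145_at	NM_013002	1373260_at	AI412606
1367887_at	NM_017024	1373260_at	AI412606
1393373_at	BI289640	1373260_at	AI412606
1389586_at	BE107169	1373260_at	AI412606
1394940_at	BI294811	1373260_at	AI412606
1398888_at	AI408819	1373260_at	AI412606
1370442_at	U25684	1373260_at	AI412606
1367576_at	S41066	1373260_at	AI412606
1372002_at	AI411352	1373260_at	AI412606
1398616_at	AI045228	1373260_at	AI412606
1367648_at	NM_013122	1373260_at	AI412606
1395249_at	BF400750	1373260_at	AI412606
1371245_a_at	BI287300	1373260_at	AI412606
1370172_at	AA892254	1373260_at	AI412606
1370240_x_at	AI179404	1373260_at	AI412606
1388608_x_at	AI577319	1373260_at	AI412606
1388795_at	AI101500	1373260_at	AI412606
1373260_at	AI412606	1367887_at	NM_017024
1373260_at	AI412606	1393373_at	BI289640
1370240_x_at	AI179404	1393373_at	BI289640
1373260_at	AI412606	1389586_at	BE107169
1373260_at	AI412606	1394940_at	BI294811
1373260_at	AI412606	1398888_at	AI408819
1373260_at	AI412606	1370442_at	U25684
1386911_at	NM_012505	1368565_at	NM_019225
1373260_at	AI412606	1367576_at	S41066
1370240_x_at	AI179404	1367681_at	NM_022523
1383294_at	BF412731	1372002_at	AI411352
1373260_at	AI412606	1372002_at	AI411352
1386911_at	NM_012505	1372002_at	AI411352
1386911_at	NM_012505	1368170_at	NM_024371
1383294_at	BF412731	1398616_at	AI045228
1373260_at	AI412606	1398616_at	AI045228
1370240_x_at	AI179404	1398616_at	AI045228
1388608_x_at	AI577319	1398616_at	AI045228
1383294_at	BF412731	1367648_at	NM_013122
1373260_at	AI412606	1367648_at	NM_013122
1386911_at	NM_012505	1367648_at	NM_013122
1370240_x_at	AI179404	1393263_at	AW522530
1373260_at	AI412606	1395249_at	BF400750
1383294_at	BF412731	1371245_a_at	BI287300
1373260_at	AI412606	1371245_a_at	BI287300
1370240_x_at	AI179404	1371245_a_at	BI287300
1388608_x_at	AI577319	1371245_a_at	BI287300
1386911_at	NM_012505	1375856_at	AI102258
1373260_at	AI412606	1370172_at	AA892254
1367624_at	NM_024403	1386911_at	NM_012505
1383294_at	BF412731	1386911_at	NM_012505
1367590_at	NM_053439	1386911_at	NM_012505
1368145_at	NM_013002	1386911_at	NM_012505
1368565_at	NM_019225	1386911_at	NM_012505
1372002_at	AI411352	1386911_at	NM_012505
1368170_at	NM_024371	1386911_at	NM_012505
1367648_at	NM_013122	1386911_at	NM_012505
1375856_at	AI102258	1386911_at	NM_012505
1367624_at	NM_024403	1370240_x_at	AI179404
1371352_at	BM391736	1370240_x_at	AI179404
1383294_at	BF412731	1370240_x_at	AI179404
1368145_at	NM_013002	1370240_x_at	AI179404
1373260_at	AI412606	1370240_x_at	AI179404
1393373_at	BI289640	1370240_x_at	AI179404
1367681_at	NM_022523	1370240_x_at	AI179404
1398616_at	AI045228	1370240_x_at	AI179404
1393263_at	AW522530	1370240_x_at	AI179404
1371245_a_at	BI287300	1370240_x_at	AI179404
1388608_x_at	AI577319	1370240_x_at	AI179404
1383294_at	BF412731	1388608_x_at	AI577319
1373260_at	AI412606	1388608_x_at	AI577319
1398616_at	AI045228	1388608_x_at	AI577319
1371245_a_at	BI287300	1388608_x_at	AI577319
1370240_x_at	AI179404	1388608_x_at	AI577319
1373260_at	AI412606	1388795_at	AI101500
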