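1367576_at	S41066	Gpx1
1367590_at	NM_053439	Ran
1367624_at	NM_024403	Atf4
1367648_at	NM_013122	Igfbp2
1367681_at	NM_022523	CD151
1367887_at	NM_017024	Lcat
1368145_at	NM_013002	Pcp4
1368170_at	NM_024371	Slc6a1
1368565_at	NM_019225	Slc1a3
1370172_at	AA892254	Sod2
1370240_x_at	AI179404	Hba1
1370442_at	U25684	Tmsbl1
1371245_a_at	BI287300	Hbb
1371352_at	BM391736	Hmgn2
1372002_at	AI411352	Gja1
1373260_at	AI412606	Caprin2
1375856_at	AI102258	EST
1386911_at	NM_012505	Atp1a2
1388608_x_at	AI577319	EST
1388795_at	AI101500	EST
1389586_at	BE107169	EST
1398888_at	AI408819	H3f3b
1383294_at	BF412731	Pdyn
1393263_at	AW522530	Snhg11
1393373_at	BI289640	Opn3
1394940_at	BI294811	Fam46a
1395249_at	BF400750	Snhg11
1398616_at	AI045228	Ap1s2
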