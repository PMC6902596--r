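gene	insertion_pos	group	name
atp1	361	g2	atp1i361g2
atp1	989	g2	atp1i989g2
atp9	87	g2	atp9i87g2
cob	372	g1	cobi372g1
cob	693	g1	cobi693g1
cob	824	g2	cobi824g2
cox1	44	g2	cox1i44g2
cox1	178	g2	cox1i178g2
cox1	375	g1	cox1i375g1
cox1	395	g1	cox1i395g1
cox1	624	g1	cox1i624g1
cox1	729	g2	cox1i729g2
cox1	732	g1	cox1i732g1
cox1	1064	g2	cox1i1064g2
cox1	1116	g1	cox1i1116g1
cox2	97	g2	cox2i97g2
cox2	281	g2	cox2i281g2
cox2	373	g1	cox2i373g1
cox2	564	g1	cox2i564g1
cox3	171	g1	cox3i171g1
nad2	156	g2	nad2i156g2
nad2	542	g2	nad2i542g2
nad3	52	g2	nad3i52g2
nad4L	100	g2	nad4Li100g2
nad4L	283	g2	nad4Li283g2
nad5	230	g1	nad5i230g1
nad5	881	g2	nad5i881g2
nad5	1242	g2	nad5i1242g2
nad7	336	g2	nad7i336g2
nad9	246	g2	nad9i246g2
rrn18	1065	g2	rrn18i1065g2
rrn26	827	g2	rrn26i827g2
rrn26	2352	g1	rrn26i2352g1
rps3	257	g2	rps3i257g2
rps14	114	g2	rps14i114g2
trnS	43	g2	trnSi43g2
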