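species	mean_peak_nm	sd_peak_nm	pred_half_pitch_nm	sd_pred_nm	obs_half_pitch_nm	sd_obs_nm	arcs_present
Anemia mexicana var. makrinii	482	27	161	9	157	8	TRUE
Antrophyum callifolium	457	29	152	10	156	13	TRUE
Cyclopeltis crenata	486	17	162	6	168	10	TRUE
Elaphoglossum herminieri	474	19	158	6	155	11	TRUE
Lindsaea borneensis	488	23	163	8	163	12	TRUE
Selliguea sp.	472	15	157	5	155	11	TRUE
Tectaria angulata	469	25	156	8	164	14	TRUE
Teratophyllum ludens	536	17	178	6	175	14	TRUE
Bulbophyllum cheiropetalum	499	26	166	9	172	18	TRUE
Dendrobium sp.	500	27	167	9	171	14	TRUE
Masdevallia caesia	458	14	152	5	156	13	TRUE
Porroglossum eduardii	487	17	162	5	164	13	TRUE
Trichosalpinx blaisdellii	485	14	162	5	166	12	TRUE
Carex paniculata	466	33	155	11	150	13	TRUE
Cyperus alternifolius	454	17	151	6	157	13	TRUE
Rhynchospora splendens	568	43	189	14	182	13	TRUE
Scleria motleyi	463	25	154	8	157	14	TRUE
Paepalanthus stegolepoides	476	40	159	14	155	23	TRUE
Phelpsiella ptericaulis	439	12	146	4	144	12	TRUE
Stegolepis pungens	449	23	150	8	158	13	TRUE
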