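name	family	accession	fbg_start	fbg_end	published_ridge	published_triad	published_ctail	published_predicted	crystal_available
Tenascin-C	tenascin	P24821	1974	2201	7	TRUE	TRUE	TRUE	FALSE
Tenascin-R	tenascin	Q92752	1128	1359	7	TRUE	TRUE	TRUE	FALSE
Tenascin-W	tenascin	Q9UQP3	1060	1300	6	TRUE	TRUE	TRUE	FALSE
Tenascin-X	tenascin	P22105	4013	4243	2	FALSE	FALSE	FALSE	TRUE
Angiopoietin-1	angiopoietin	Q15389	271	498	4	FALSE	FALSE	TRUE	TRUE
Angiopoietin-2	angiopoietin	O15123	269	496	4	FALSE	FALSE	TRUE	FALSE
Angiopoietin-4	angiopoietin	Q9Y264	276	503	1	FALSE	FALSE	FALSE	FALSE
Angiopoietin-like protein 1	angiopoietin-like	O95841	264	491	5	TRUE	FALSE	TRUE	FALSE
Angiopoietin-like protein 2	angiopoietin-like	Q9UKU9	266	493	5	FALSE	FALSE	TRUE	FALSE
Angiopoietin-like protein 3	angiopoietin-like	Q9Y5C1	233	460	0	FALSE	FALSE	FALSE	FALSE
Angiopoietin-like protein 4	angiopoietin-like	Q9BY76	179	406	0	FALSE	FALSE	FALSE	FALSE
Angiopoietin-like protein 5	angiopoietin-like	Q86XS5	161	388	2	FALSE	FALSE	FALSE	FALSE
Angiopoietin-like protein 6	angiopoietin-like	Q8NI99	243	470	5	FALSE	FALSE	TRUE	FALSE
Angiopoietin-like protein 7	angiopoietin-like	O43827	119	346	2	FALSE	FALSE	FALSE	TRUE
FIBCD-1	other	Q8N539	234	461	2	FALSE	FALSE	FALSE	TRUE
Fibrinogen alpha chain	fibrinogen chain	P02671	639	866	2	FALSE	FALSE	FALSE	TRUE
Fibrinogen beta chain	fibrinogen chain	P02675	264	491	3	TRUE	FALSE	TRUE	TRUE
Fibrinogen gamma chain	fibrinogen chain	P02679	226	453	4	FALSE	FALSE	TRUE	FALSE
Fibrinogen-like protein 1	other	Q08830	85	312	5	FALSE	FALSE	TRUE	FALSE
Fibroleukin	other	Q14314	212	439	5	FALSE	FALSE	TRUE	TRUE
Ficolin-1	ficolin	O00602	99	326	4	FALSE	FALSE	TRUE	TRUE
Ficolin-2	ficolin	Q15485	86	313	2	FALSE	FALSE	FALSE	TRUE
Ficolin-3	ficolin	O75636	72	299	2	FALSE	FALSE	FALSE	FALSE
MFAP4	other	P55083	28	255	2	TRUE	FALSE	FALSE	FALSE
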