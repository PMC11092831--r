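cptid	rsid	chr	bp	effect_allele	other_allele	eaf	beta	se	p	info	n
1:100:A:G	rs1	1	100	A	G	0.3	0.1	0.02	5e-7	0.99	1000
1:200:C:T	rs2	1	200	C	T	0.005	0.05	0.02	0.012	0.95	1000
1:300:G:A	rs3	1	300	G	A	0.4	-0.02	0.02	0.32	0.4	1000
1:400:T:C	rs4	1	400	T	C	0.25	0.03	0.03	0.31	0.92	100
1:400:T:G	rs5	1	400	T	G	0.25	0.04	0.03	0.18	0.97	200
2:100:A:C	rs6	2	100	A	C	0.1	-0.07	0.02	4e-4	0.88	1000
2:200:G:T	rs7	2	200	G	T	0.45	0.01	0.02	0.62	0.91	1000
2:300:C:A	rs8	2	300	C	A	0.2	0.02	0.02	0.33	0.93	1000
3:100:T:A	rs9	3	100	T	A	0.35	-0.05	NA	0.012	0.9	1000
3:200:G:C	rs10	3	200	G	C	0.15	0.06	0.02	0.0027	0.96	1000
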