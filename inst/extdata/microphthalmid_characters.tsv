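index	group	subject	predicates
1	Prostomium	Shape	0=Rectangular, sides parallel|1=Trapezoidal, wider posteriorly|2=Ovoid
2	Prostomium	Posterior margin	0=Well defined|1=Indistinct medially
3	Prostomium	Antennae number	0=Three|1=Two
4	Prostomium	Antennae shape	0=Cylindrical, tapered|1=Regularly constricted (moniliform)
5	Prostomium	Median antenna position	0=Anterior, over the anterior margin|1=Central|2=Posterior, towards the posterior margin
6	Prostomium	Palps	0=Present|1=Absent
7	Prostomium	Palp articulation	0=Biarticulate|1=Simple
8	Prostomium	Palps position	0=Ventro-terminal|1=Distal, on the anterior prostomial margin|2=Ventral
9	Prostomium	Eyes	0=Present|1=Absent
10	Prostomium	Number of eyes	0=Two pairs|1=One pair
11	Anterior segments and cirri	Relative fusion between successive tentacular segments	0=Segments indistinct, cirri anteriorly displaced|1=Segments distinct, cirri regularly separated
12	Anterior segments and cirri	Pairs of cirri	0=Eight|1=Six|2=Four|3=Three|4=Two
13	Anterior segments and cirri	Size of cirri	0=Longer than body width|1=As long as body width|2=Shorter than body width
14	Anterior segments and cirri	Relative size of anterior cirri regarding dorsal cirri of chaetigers 1-2	0=Slightly longer or about the same size|1=Markedly longer|2=Shorter
15	Anterior segments and cirri	Cirri base	0=Cylindrical|1=Subconical
16	Parapodia	Alignment	0=All neuropodia lateral|1=Few anterior neuropodia dorsal|2=First neuropodia ventral
17	Parapodia	Dorsal cirri shape	0=Tapered|1=Digitate|2=Subdistally swollen|3=(state present in matrix, not listed among predicates)
18	Parapodia	Dorsal cirrostyle margins	0=Articulated|1=Smooth
19	Parapodia	Dorsal cirrophore	0=Cylindrical|1=Subconical|2=Globose or scale-shaped
20	Parapodia	Dorsal cirri size	0=Three or more times longer than ventral cirri|1=Twice as long as ventral cirri|2=As long as ventral cirri, or shorter
21	Anterior parapodia chaetae	First chaetiger chaetae	0=Similar to chaetae in chaetiger 6|1=Different from chaetiger 6
22	Anterior parapodia chaetae	Anterior neurohooks	0=Absent|1=Present
23	Anterior parapodia chaetae	Anterior neurohook blade	0=Compressed, as long as wide|1=Tapered, markedly longer than wide
24	Median parapodia notochaetae	Presence	0=Present|1=Absent
25	Median parapodia notochaetae	Number of notochaetae	0=1-4|1=Five or more
26	Median parapodia notochaetae	Notochaetae capillaries	0=Present|1=Absent
27	Median parapodia notochaetae	Notochaetae spines	0=Absent|1=Present
28	Median parapodia notochaetae	Notochaetae hooks	0=Absent|1=Present
29	Median parapodia notochaetae	Modified notochaetae denticulates	0=Absent|1=Present
30	Median parapodia notochaetae	Modified notochaetae pectinates	0=Absent|1=Present
31	Median parapodia neurochaetae	Compound neurochaetae	0=Present|1=Absent
32	Median parapodia neurochaetae	Handle	0=Chambered|1=Solid
33	Median parapodia neurochaetae	Tips	0=Only bidentate|1=Only unidentate|2=Both uni- and bidentate
34	Median parapodia neurochaetae	Blades size in the same chaetiger	0=Heterogeneous|1=Homogeneous
35	Median parapodia neurochaetae	Neurochaetae spines	0=Absent|1=Present
36	Median parapodia neurochaetae	Tips of spines	0=Only unidentate|1=Only bidentate|2=Both uni- and bidentate
37	Median parapodia neurochaetae	Denticulate neurochaetae	0=Absent|1=Present
38	Median parapodia neurochaetae	Size in the same chaetiger	0=Heterogeneous|1=Homogeneous
39	Posterior end	Pygidium margin	0=Not projected into an anal membrane|1=Transformed into an anal membrane
40	Posterior end	Anal membrane lobes	0=Foliose|1=Lobate|2=Convoluted
41	Posterior end	Anal membrane continuity	0=Continuous|1=Medially notched|2=Laterally separated or bipartite
42	Posterior end	Anal membrane margin	0=Smooth|1=Crenulated or fimbriated
43	Posterior end	Anal cirri	0=Present|1=Absent
44	Posterior end	Shape of anal cirri	0=Tapered|1=Basally swollen|2=Medially or subdistally swollen
45	Posterior end	Size of anal cirri	0=Two to five times longer than pygidial width|1=As long as pygidium width|2=Smaller than pygidium width
46	Male copulatory organs	Presence	0=Absent|1=Present
47	Male copulatory organs	Position	0=On dorsal surface|1=On prostomium|2=Intersegmental
48	Habitat	Symbiotic life	0=Free-living|1=Living in association with other invertebrates
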