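# Synthetic sentiment lexicon in SentiWordNet 3.0 file layout.
# Scores are synthetic fixture values, not SentiWordNet's.
# POS	ID	PosScore	NegScore	SynsetTerms	Gloss
a	00000001	0.7	0	good#1	synthetic positive entry
a	00000002	0.8	0	great#1	synthetic positive entry
a	00000003	0.75	0	happy#1	synthetic positive entry
a	00000004	0.7	0	glad#1	synthetic positive entry
a	00000005	0.7	0	hopeful#1	synthetic positive entry
a	00000006	0.8	0	wonderful#1	synthetic positive entry
a	00000007	0.75	0	thankful#1	synthetic positive entry
a	00000008	0.8	0	grateful#1	synthetic positive entry
a	00000009	0.7	0	blessed#1	synthetic positive entry
a	00000010	0.7	0	relieved#1	synthetic positive entry
a	00000011	0.6	0	encouraging#1	synthetic positive entry
a	00000012	0.6	0	lucky#1	synthetic positive entry
a	00000013	0.6	0	hope#1	synthetic positive entry
a	00000014	0.7	0	love#1	synthetic positive entry
a	00000015	0.6	0	positive#1	synthetic positive entry
a	00000016	0.5	0	better#1	synthetic positive entry
a	00000017	0.5	0	comfort#1	synthetic positive entry
a	00000018	0	0.7	worried#1	synthetic negative entry
a	00000019	0	0.8	scared#1	synthetic negative entry
a	00000020	0	0.75	afraid#1	synthetic negative entry
a	00000021	0	0.7	anxious#1	synthetic negative entry
a	00000022	0	0.7	sad#1	synthetic negative entry
a	00000023	0	0.8	depressed#1	synthetic negative entry
a	00000024	0	0.8	terrible#1	synthetic negative entry
a	00000025	0	0.8	awful#1	synthetic negative entry
a	00000026	0	0.85	hopeless#1	synthetic negative entry
a	00000027	0	0.9	devastated#1	synthetic negative entry
a	00000028	0	0.7	stressed#1	synthetic negative entry
a	00000029	0	0.7	frustrated#1	synthetic negative entry
a	00000030	0	0.7	upset#1	synthetic negative entry
a	00000031	0	0.6	nervous#1	synthetic negative entry
a	00000032	0	0.8	miserable#1	synthetic negative entry
a	00000033	0	0.6	lonely#1	synthetic negative entry
a	00000034	0	0.7	fear#1	synthetic negative entry
r	00000035	0.5	0	well#1	synthetic multi-sense entry, sense 1
r	00000036	0	0	well#2	synthetic multi-sense entry, sense 2
a	00000037	0.6	0.1	bittersweet#1	synthetic mixed entry
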