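family	ec	substrate
GH13	3.2.1.1	starch
GH13	3.2.1.133	starch
GH13	3.2.1.20	starch
GH15	3.2.1.3	starch
GH57	3.2.1.1	starch
GH16	3.2.1.39	beta-glucan
GH16_3	3.2.1.39	beta-glucan
GH17	3.2.1.39	beta-glucan
GH55	3.2.1.58	beta-glucan
GH5	3.2.1.4	cellulose
GH6	3.2.1.4	cellulose
GH8	3.2.1.4	cellulose
GH9	3.2.1.4	cellulose
GH48	3.2.1.176	cellulose
GH10	3.2.1.8	xylan
GH11	3.2.1.8	xylan
GH43	3.2.1.37	xylan
GH67	3.2.1.139	xylan
PL1	4.2.2.2	pectin
PL9	4.2.2.2	pectin
GH28	3.2.1.15	pectin
CE8	3.1.1.11	pectin
GH18	3.2.1.14	chitin
GH19	3.2.1.14	chitin
GH20	3.2.1.52	chitin
PL6	4.2.2.3	alginate
PL7	4.2.2.3	alginate
PL17	4.2.2.3	alginate
GH29	3.2.1.51	fucoidan
GH95	3.2.1.51	fucoidan
GH50	3.2.1.81	agarose
GH86	3.2.1.81	agarose
GH37	3.2.1.28	trehalose
GH65	3.2.1.28	trehalose
GH32	3.2.1.26	fructan
GH68	2.4.1.9	fructan
GH36	3.2.1.22	alpha-galactan
GH2	3.2.1.23	beta-galactan
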