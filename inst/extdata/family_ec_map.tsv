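family	ec
GH13	3.2.1.1
GH13	3.2.1.133
GH13	3.2.1.20
GH15	3.2.1.3
GH57	3.2.1.1
GH16	3.2.1.39
GH16_3	3.2.1.39
GH17	3.2.1.39
GH55	3.2.1.58
GH5	3.2.1.4
GH6	3.2.1.4
GH8	3.2.1.4
GH9	3.2.1.4
GH48	3.2.1.176
GH10	3.2.1.8
GH11	3.2.1.8
GH43	3.2.1.37
GH67	3.2.1.139
PL1	4.2.2.2
PL9	4.2.2.2
GH28	3.2.1.15
CE8	3.1.1.11
GH18	3.2.1.14
GH19	3.2.1.14
GH20	3.2.1.52
PL6	4.2.2.3
PL7	4.2.2.3
PL17	4.2.2.3
GH29	3.2.1.51
GH95	3.2.1.51
GH50	3.2.1.81
GH86	3.2.1.81
GH37	3.2.1.28
GH65	3.2.1.28
GH32	3.2.1.26
GH68	2.4.1.9
GH36	3.2.1.22
GH2	3.2.1.23
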