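breed	group	n	mean	sd
WL	all	527	679.9	768.17
WL	high	40	1501.70	1678.05
WL	low	40	293.91	58.29
BY	all	726	628.2	923.987
BY	high	40	1888.84	1189.55
BY	low	40	302.55	24.91
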