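shape	bin_1	bin_2	bin_3	bin_4	bin_5	bin_6	bin_7	bin_8	mean	sd	skewness	kurtosis
1	0	0	0.05	0.45	0.45	0.05	0	0	0	0.167705098312484	0	-0.222222222222222
2	0.02	0.08	0.15	0.25	0.25	0.15	0.08	0.02	0	0.378318648760539	0	-0.367994508113881
3	0.1	0.3	0.34	0.15	0.07	0.03	0.01	0	-0.395	0.311608729017658	0.740203798884857	0.546040106444248
4	0	0.01	0.03	0.07	0.15	0.34	0.3	0.1	0.395	0.311608729017658	-0.740203798884857	0.546040106444248
5	0.01	0.15	0.3	0.04	0.04	0.3	0.15	0.01	0	0.467038542306735	0	-1.54167863974844
6	0.22	0.15	0.08	0.05	0.05	0.08	0.15	0.22	0	0.691465834296967	0	-1.65756760220428
7	0.28	0.17	0.07	0.04	0.04	0.06	0.13	0.21	-0.09	0.709771089859259	0.222507139677717	-1.66153315284844
8	0.21	0.13	0.06	0.04	0.04	0.07	0.17	0.28	0.09	0.709771089859259	-0.222507139677717	-1.66153315284844
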