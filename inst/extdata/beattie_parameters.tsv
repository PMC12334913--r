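name	value	unit	lower	upper
g	2.44	1e-01*uS	NA	NA
p1	1.68	1e-04*ms^-1	1.39	12.9
p2	8.06	1e-02*mV^-1	1.08	8.49
p3	4.34	1e-05*ms^-1	2.77	32.3
p4	4.07	1e-02*mV^-1	2.48	4.56
p5	9.07	1e-02*ms^-1	6.4	19.9
p6	2.67	1e-02*mV^-1	2.18	3.87
p7	7.32	1e-03*ms^-1	7.07	10.9
p8	3.22	1e-02*mV^-1	2.89	3.39
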