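name	value	unit	lower	upper
g	2.11	1e-01*uS	NA	NA
kb	0.67	1e-02*ms^-1	0.67	99993
kf	1.31	1e-02*ms^-1	1.31	99550
q1	1.24	1e-01*ms^-1	1.24	1.81
q2	1.56	1e-02*mV^-1	1.55	2.06
q3	0.04	1e-02*ms^-1	0.03	1.02
q4	10.9	1e-02*mV^-1	1e-04	10.9
q5	0.24	1e-02*ms^-1	0.23	364
q6	1e-04	1e-02*mV^-1	1e-04	6.44
q7	3.15	1e-04*ms^-1	1.29	7.69
q8	3.99	1e-02*mV^-1	2.97	3.99
q9	5.75	1e-03*ms^-1	3.55	5.75
q10	2.89	1e-02*mV^-1	2.89	3.34
q11	0.28	1e-02*ms^-1	0.007	1458
q12	10.7	1e-02*mV^-1	1.16	11.8
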