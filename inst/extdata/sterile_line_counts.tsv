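line	f2_wildtype	f2_carrier	f3_scored	f3_wildtype	f3_star_plus	f3_sterile
R002	2	3	21	3	8	10
R010	2	2	23	13	7	3
R015	1	3	21	1	15	5
R019	1	7	56	9	34	13
R103	1	6	44	5	18	21
R152	0	6	35	0	10	25
R176	2	0	4	4	0	0
R182	1	4	34	6	23	5
R194	3	1	30	24	5	1
R247	1	0	4	4	0	0
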