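cyp	pdb_id	class_label
1A2	2HI4	classII
2A6	1Z10	classII
2A13	2P85	classII
2B4	1SUO	classII
2C5	1N6B	classII
2C8	1PQ2	classII
2C9	1OG2	classII
2D6	2F9Q	classII
2R1	2OJD	classII
3A4	1TQN	classII
102A1	1BU7	classII
175A1	1N97	classII
51B1	1E9X	classI
101D	2CPP	classI
107A1	1OXA	classI
107L1	2BVJ	classI
108A	1CPT	classI
119	1IO7	classI
154A1	1ODO	classI
154C1	1GWI	classI
158A1	2DKK	classI
158A2	1S1F	classI
165B3	1LFK	classI
165C4	1UED	classI
167A1	1Q5D	classI
176A1	1T2B	classI
199A2	2FR7	classI
245A1	2Z3T	classI
8A	2IAG	other
55A2	1CL6	other
152A1	1IZO	other
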