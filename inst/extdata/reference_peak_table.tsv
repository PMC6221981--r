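cue	group	distractor	channel	n2	n2_sd	p3	p3_sd	n2p3	n2p3_sd
Go	Control	Emotional	F3	-5.3	3.8	1.5	3.2	6.8	3.3
Go	Control	Emotional	F4	-3.9	4.4	3.1	2.8	7.0	3.3
Go	Control	Neutral	F3	-5.1	3.8	1.4	3.1	6.5	3.3
Go	Control	Neutral	F4	-3.6	4.7	2.8	3.0	6.4	3.0
Go	OFC	Emotional	F3	-3.5	6.0	4.4	7.2	7.9	4.0
Go	OFC	Emotional	F4	-2.5	4.9	5.6	5.2	8.2	3.5
Go	OFC	Neutral	F3	-3.6	5.6	4.7	7.0	8.3	4.7
Go	OFC	Neutral	F4	-2.8	4.8	5.7	5.3	8.4	4.4
NoGo	Control	Emotional	F3	-3.0	2.1	7.4	4.2	10.4	4.5
NoGo	Control	Emotional	F4	-3.0	2.3	6.3	3.8	9.3	4.6
NoGo	Control	Neutral	F3	-2.6	2.7	7.1	3.9	9.7	4.1
NoGo	Control	Neutral	F4	-2.8	2.9	5.8	3.7	8.5	4.1
NoGo	OFC	Emotional	F3	-2.3	3.6	10.4	4.8	12.7	5.5
NoGo	OFC	Emotional	F4	-2.6	3.9	10.3	4.9	12.8	5.2
NoGo	OFC	Neutral	F3	-1.9	3.7	10.1	4.4	12.0	5.2
NoGo	OFC	Neutral	F4	-1.9	3.3	10.2	4.7	12.0	5.0
Go	Control	Emotional	C3	-6.5	3.9	0.7	3.0	7.2	4.0
Go	Control	Emotional	C4	-4.3	3.2	3.2	4.3	7.5	4.3
Go	Control	Neutral	C3	-6.5	3.9	0.6	3.1	7.1	3.8
Go	Control	Neutral	C4	-4.3	3.5	2.7	3.8	7.1	4.0
Go	OFC	Emotional	C3	-4.7	6.4	3.4	6.3	8.2	3.8
Go	OFC	Emotional	C4	-4.1	6.1	4.5	4.8	8.6	4.4
Go	OFC	Neutral	C3	-4.8	6.2	3.5	6.1	8.4	4.2
Go	OFC	Neutral	C4	-4.6	5.8	4.9	5.0	9.5	4.6
NoGo	Control	Emotional	C3	-2.1	2.2	7.6	3.9	9.6	4.0
NoGo	Control	Emotional	C4	-1.8	1.7	7.0	4.1	8.7	4.6
NoGo	Control	Neutral	C3	-1.9	2.3	7.1	3.8	9.0	3.9
NoGo	Control	Neutral	C4	-1.6	1.7	6.5	4.0	8.1	4.3
NoGo	OFC	Emotional	C3	-1.5	3.8	9.1	3.6	10.7	5.0
NoGo	OFC	Emotional	C4	-2.0	3.7	9.1	4.5	11.1	4.8
NoGo	OFC	Neutral	C3	-1.1	4.3	9.2	3.6	10.3	5.1
NoGo	OFC	Neutral	C4	-1.2	3.8	8.9	4.4	10.1	5.0
Go	Control	Emotional	P3	-2.8	4.7	4.4	3.6	7.2	4.7
Go	Control	Emotional	P4	-1.4	4.3	5.5	3.8	6.9	4.6
Go	Control	Neutral	P3	-2.9	5.1	4.0	4.0	6.9	4.8
Go	Control	Neutral	P4	-1.2	4.8	5.0	4.1	6.2	4.5
Go	OFC	Emotional	P3	-2.7	4.4	5.6	4.4	8.3	3.2
Go	OFC	Emotional	P4	-2.6	3.7	5.9	3.4	8.5	3.8
Go	OFC	Neutral	P3	-3.2	4.5	5.2	4.0	8.4	3.1
Go	OFC	Neutral	P4	-2.8	3.8	6.0	3.3	8.8	3.7
NoGo	Control	Emotional	P3	-0.7	3.7	6.1	4.6	6.9	4.0
NoGo	Control	Emotional	P4	-0.4	3.8	6.4	4.0	6.8	4.6
NoGo	Control	Neutral	P3	-0.9	4.0	6.2	3.9	7.1	3.8
NoGo	Control	Neutral	P4	-0.5	3.8	6.4	3.8	6.9	4.3
NoGo	OFC	Emotional	P3	-0.9	3.4	7.2	3.5	8.1	3.8
NoGo	OFC	Emotional	P4	-0.4	2.5	7.5	3.6	7.9	3.1
NoGo	OFC	Neutral	P3	-0.7	4.1	7.0	3.6	7.7	4.2
NoGo	OFC	Neutral	P4	-0.3	2.8	7.4	3.4	7.6	3.2
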