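variable	level	type	total_N	total_M	total_S	g1_N	g1_M	g1_S	g2_N	g2_M	g2_S	p	test
radiculopathy		total	30			15			15				
radiculopathy	yes	cat	15			6			7				
radiculopathy	no	cat	15			7			8				
level of single-level fusion		total	69			33			36				
level of single-level fusion	L2-3	cat				3			1			0.694	NS
level of single-level fusion	L3-4	cat				8			8			0.694	NS
level of single-level fusion	L4-5	cat				17			37			0.694	NS
level of single-level fusion	L5-S1	cat				5			12			0.694	NS
fracture classification		total	24			12			12				
fracture classification	A3.1	cat				8			7			0.203	chisq
fracture classification	A3.2	cat				4			5			0.203	chisq
ionized calcium		total	62			20			42				
ionized calcium		cont	62	1.23	0.04	20	1.32	0.05	42	1.21	0.05		
left step time		total	20			10			10				
left step time		cont				10	0.65	0.03	10	0.66	0.02	0.624	t-test
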