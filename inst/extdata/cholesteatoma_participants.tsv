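family_id	sample_id	age	age_is_surgery_proxy	bilateral	sex	relationship
1	1a	28	N	Y	female	Sister
1	1b	30	Y	N	male	Child
2	2a	23	N	Y	male	Index
2	2b	11	N	N	male	Brother
3	3a	44	Y	N	female	Index
3	3b	3	N	N	female	Child
3	3c	6	N	Y	female	Sister
4	4a	35	N	N	male	Index
4	4b	40	Y	N	male	Brother
5	5a	1	N	Y	female	Index
5	5b	36	N	N	male	Child
6	6a	10	N	N	female	Index
6	6b	5	N	N	female	Maternal aunt
7	7a	1	N	N	female	Index
7	7b	63	N	N	male	Maternal grandfather
8	8a	11	N	N	female	Index
8	8b	6	N	N	male	Brother
9	9a	42	Y	N	female	Index
9	9b	44	Y	N	female	Mother
10	10a	1	N	Y	female	Index
10	10b	5	N	Y	female	Granddaughter
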