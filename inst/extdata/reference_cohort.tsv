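group	subset	role	subject_id	n_segments
CPS	1	training	Su12	102
CPS	2	training	Su01	73
CPS	3	training	Su03	78
CPS	4	training	Su05	81
CPS	5	training	Su17	33
CPS	6	training	Su10	34
CPS	7	training	Su18	37
CPS	8	training	Su09	40
CPS	9	training	Su07	72
CPS	10	training	Su14	84
CPS	11	training	Su08	117
CPS	12	training	Su04	125
CPS	13	training	Su16	144
CPS	14	training	Su15	169
CPS	15	testing	Su02	75
CPS	16	testing	Su04	42
SPS	1	training	Su11	105
SPS	2	training	Su16	77
SPS	3	training	Su32	123
SPS	4	training	Su33	146
SPS	5	training	Su14	51
SPS	6	training	Su22	57
SPS	7	training	Su09	58
SPS	8	training	Su18	59
SPS	9	training	Su15	64
SPS	10	training	Su12	89
SPS	11	training	Su07	117
SPS	12	training	Su23	148
SPS	13	training	Su03	150
SPS	14	training	Su06	168
SPS	15	testing	Su24	34
SPS	16	testing	Su31	80
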