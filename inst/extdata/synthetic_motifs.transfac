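ID synthetic_oct_like
NA synthetic_POU_factor
P0	A	C	G	T
01	85	5	5	5
02	5	5	5	85
03	5	5	85	5
04	85	5	5	5
05	5	5	5	85
06	5	85	5	5
07	85	5	5	5
08	85	5	5	5
//
ID synthetic_sox_like
NA synthetic_HMG_factor
P0	A	C	G	T
01	5	85	5	5
02	85	5	5	5
03	5	5	5	85
04	5	5	5	85
05	5	5	85	5
06	5	5	5	85
07	5	5	5	85
//
ID synthetic_fkh_like
NA synthetic_forkhead_factor
P0	A	C	G	T
01	5	5	5	85
02	5	5	85	5
03	5	5	5	85
04	5	5	5	85
05	5	5	85	5
06	85	5	5	5
07	5	85	5	5
08	5	5	5	85
//
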