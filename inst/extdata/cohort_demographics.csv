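participant,age,sex,ear,implant_type,array,time_of_use_months,etiology
1,65,M,RIGHT,Neuro Zti,EVO,32,Unknown
2,60,F,LEFT,Neuro Zti,EVO,35,Sudden HL
3,44,F,RIGHT,Neuro Zti,EVO,42,Unknown
4,65,F,LEFT,Neuro Zti,EVO,45,Ototoxic
5,64,M,LEFT,Neuro Zti,EVO,32,Unknown
6,69,F,LEFT,Neuro Zti,EVO,41,Unknown
7,45,M,LEFT,Neuro Zti,EVO,32,Possible hepatitis
8,52,F,RIGHT,Neuro Zti,EVO,37,Hepatitis disease
9,39,F,LEFT,Neuro Zti,EVO,35,Unknown
10,45,M,LEFT,Neuro Zti,EVO,50,Unknown
11,61,M,LEFT,Neuro Zti,EVO,51,Unknown
12,53,M,RIGHT,Neuro Zti,EVO,42,Head trauma
13,59,F,RIGHT,Neuro Zti,EVO,39,Unknown
14,27,F,RIGHT,Neuro Zti,EVO,12,Unknown
15,63,M,LEFT,Neuro Zti,EVO,58,Unknown
16,48,F,RIGHT,Neuro Zti,EVO,59,Meniere disease
17,36,F,RIGHT,Neuro Zti,EVO,42,Unknown
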