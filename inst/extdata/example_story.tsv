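# duration: 6
token	onset	wordLength	verb	character.harry
The	0	3	0	0
boy	0.5	3	0	0
who	1	3	0	0
lived	1.5	5	1	0
Harry	2	5	0	1
raised	2.5	6	1	0
his	3	3	0	0
wand	3.5	4	0	0
and	4	3	0	0
waited	4.5	6	1	0
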