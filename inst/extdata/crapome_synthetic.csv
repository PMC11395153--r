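accession,Ave SC,Num of Exp
P04264,37.2,411
P35908,28.4,388
P13645,22.9,352
P00761,41.0,405
P02768,33.5,390
SYNP00001,1.0,12
SYNP00002,5.0,30
SYNP00003,6.0,41
SYNP00004,40.0,210
SYNP00005,0.5,3
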