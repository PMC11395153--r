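# Common affinity-purification contaminants (keratins, serum, proteases)
P04264
P35908
P13645
P35527
P02533
P08779
P04259
P02538
P19013
Q15323
P00761
P07477
P02768
P00883
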