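parameter,E1,E2,E3,E4,E5
Cover,2,5,5,4,4
Food availability/Prey base,2,4,3,3,5
Water availability,2,2,4,1,4
Presence of roads,1,1,0,1,3
Human habitation,1,3,2,4,5
Presence of railway track,1,0,0,1,2
Slope,0,0,0,0,1
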