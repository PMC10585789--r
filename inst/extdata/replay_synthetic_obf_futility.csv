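stage,t,control_events,control_n,treat_events,treat_n
1,0.2,121,366,112,366
2,0.4,242,732,227,731
3,0.6,362,1098,346,1097
4,0.8,483,1463,471,1463
5,1.0,604,1829,594,1829
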