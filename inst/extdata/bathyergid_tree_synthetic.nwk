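(((((BJ:1,BS:1):1,GC:2):1,(((CHH:0.8,CHN:0.8):0.4,CHP:1.2):1.3,((CM:0.9,(CA:0.8,CAN:0.8):0.2):0.5,((CB:0.8,CDM:0.8):0.3,CD:1.1):0.3):1.2):0.7):0.8,HA:3.8):0.7,HG:4.5);
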