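(((((sp01:1,sp02:1):4,sp03:5):5,(sp04:2,sp05:2):8):5,((sp06:3,sp07:3):6,sp08:9):6):10,((sp09:4,sp10:4):8,sp11:12):13);
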