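Component	maxValue
HeLa lysate	940
Accessory proteins	200
Reaction mix	380
DNA	480
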