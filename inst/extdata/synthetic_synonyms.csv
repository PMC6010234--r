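variant,canonical
item 001,item001
item-002,item002
item oo3,item003
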