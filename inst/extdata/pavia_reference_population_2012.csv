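gender,count
M,258596
F,277070
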