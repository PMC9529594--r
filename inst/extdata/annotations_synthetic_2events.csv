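label,is_bruxism,onset_s,offset_s
mouth_open,FALSE,0,2
blink_double,FALSE,4,6
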