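origin,low,medium,high
low,361,341,142
medium,68,220,137
high,17,112,171
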