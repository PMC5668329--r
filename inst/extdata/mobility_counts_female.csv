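origin,low,medium,high
low,347,414,126
medium,68,324,172
high,18,103,199
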