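method,HOTA,MOTA,IDF1,IDS
baseline,57.7,64.3,51.8,447
attention_only,77.6,76.7,78.6,464
cascade_only,78.4,74.3,82.7,54
full,82.9,80.9,85.1,24
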