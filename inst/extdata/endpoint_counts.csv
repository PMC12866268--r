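endpoint,events,n
fpe,93,213
successful_recan,173,213
excellent_outcome,61,213
sah,38,213
ph2,10,213
severe_ht,47,213
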