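cohort	n
eoo_sp	463
vlf	293
controls	480
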