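sex	n_white	n_total
male	176	179
female	285	287
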