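tissue	count
ovary	23896
oviduct	23438
cervix	8111
cornua_uteri	7971
corpus_uteri	20564
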