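stratum,arm,events,n
consistent,control,40,60
consistent,fear,35,60
consistent,social,45,59
inconsistent,control,18,50
inconsistent,fear,28,58
inconsistent,social,29,57
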