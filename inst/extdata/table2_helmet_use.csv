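wave,arm,events,n
baseline,control,69,130
baseline,fear,69,131
baseline,social,69,130
wk3,control,62,113
wk3,fear,62,117
wk3,social,70,122
wk6,control,58,110
wk6,fear,63,118
wk6,social,74,116
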