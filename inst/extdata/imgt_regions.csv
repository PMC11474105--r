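"region","from","to"
"CDR1",27,38
"CDR2",56,65
"CDR3",105,117
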