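# Assessment & Plan header patterns, one regex per line, tried in order.
# Case-insensitive; matched at line starts first, then anywhere.
assessment and plan
assessment & plan
a&p
assessment:
impression and plan
impression:
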