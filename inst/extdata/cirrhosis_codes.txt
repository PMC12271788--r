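# ICD codes marking cirrhosis (prefix wildcard with trailing *)
K74.6*
K74.3
K74.4
K74.5
K70.3*
K71.7
# legacy ICD-9
571.2
571.5
571.6
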