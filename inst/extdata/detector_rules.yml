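# Detector configuration: keyword lexicon and NegEx-style negation rules.
# Edit freely; read with read_detector_rules().
lexicon:
  - pattern: '\bNASH\b'
    label: MASH
    case_sensitive: true
  - pattern: '\bMASH\b'
    label: MASH
    case_sensitive: true
  - pattern: '\bnon[- ]?alcoholic steatohepatitis\b'
    label: MASH
    case_sensitive: false
  - pattern: '\bmetabolic dysfunction[\s–—-]+associated steatohepatitis\b'
    label: MASH
    case_sensitive: false
  - pattern: '\bsteatohepatitis\b'
    label: MASH
    case_sensitive: false
pre_triggers:
  - no evidence of
  - no evidence for
  - without evidence of
  - no signs of
  - no history of
  - negative for
  - not consistent with
  - rule out
  - ruled out
  - r/o
  - denies
  - denied
  - "no"
  - "not"
post_triggers:
  - is ruled out
  - was ruled out
  - has been ruled out
  - ruled out
  - is excluded
  - unlikely
terminators:
  - but
  - however
  - although
  - though
  - except
  - ";"
  - ":"
scope_window: 6
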