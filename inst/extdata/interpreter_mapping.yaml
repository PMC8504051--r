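# Default raw-verdict -> signed-score mapping for the four interpreter
# channels. Positive = pathogenic, negative = benign, 0 = VUS/unknown.
# Edit freely; every pipeline manifest records the md5 of the mapping in
# force. Identical to default_interpreter_mapping().
InterVar:
  type: categorical
  map:
    pathogenic: 7.8
    likely_pathogenic: 3.9
    uncertain_significance: 0
    likely_benign: -3.9
    benign: -7.8
ClinVar:
  type: categorical
  map:
    pathogenic: 6.2
    likely_pathogenic: 3.1
    uncertain_significance: 0
    likely_benign: -3.1
    benign: -6.2
SIFT:
  # score in [0,1]; < 0.05 is conventionally deleterious
  type: numeric
  threshold: 0.05
  scale: 6.1
  direction: lower_damaging
CADD:
  # phred-scaled; >= 20 is conventionally damaging
  type: numeric
  threshold: 20
  scale: 5
  direction: higher_damaging
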