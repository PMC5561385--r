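# Default sedative classification rule set: antipsychotics (N05A, excluding
# lithium N05AN and prochlorperazine N05AB04) plus benzodiazepines and
# related drugs. Edit include/exclude to audit other medication classes.
include:
  - prefix: N05A
    class: ANTIPSYCHOTIC
  - prefix: N05BA
    class: BENZODIAZEPINE
  - prefix: N05CD
    class: BENZODIAZEPINE
  - prefix: N05CF
    class: BENZODIAZEPINE
  - prefix: N03AE01
    class: BENZODIAZEPINE
exclude:
  - N05AN
  - N05AB04
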