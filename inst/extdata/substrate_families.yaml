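# Gene-family membership per substrate class, used for completeness-normalized
# copy totals (profile matrix) and the amylase / exopeptidase count rules.
# Hemicellulose is the union of the xylan, mannan and xyloglucan lists,
# each family counted once.
substrate_classes:
  cellulose:
    - CAZY:GH5
    - CAZY:GH9
    - CAZY:GH44
    - CAZY:GH45
    - CAZY:GH48
    - CAZY:GH6
    - CAZY:GH7
    - CAZY:GH1
    - CAZY:GH3
  hemicellulose:
    - CAZY:GH10
    - CAZY:GH11
    - CAZY:GH8
    - CAZY:GH43
    - CAZY:GH39
    - CAZY:GH52
    - CAZY:GH26
    - CAZY:GH113
    - CAZY:GH134
    - CAZY:GH2
    - CAZY:GH1
    - CAZY:GH74
    - CAZY:GH16
    - CAZY:GH12
    - CAZY:GH31
    - CAZY:GH3
  starch:
    - CAZY:GH13
    - CAZY:GH57
    - CAZY:GH119
    - CAZY:GH15
    - CAZY:GH4
    - CAZY:GH31
    - CAZY:GH97
  chitin:
    - CAZY:GH18
    - CAZY:GH19
    - CAZY:GH20
    - CAZY:CE4
    - CAZY:GH46
    - CAZY:GH75
    - CAZY:GH8
    - CAZY:GH35
  protein:
    - MEROPS:M01
    - MEROPS:M14
    - MEROPS:M17
    - MEROPS:M20
    - MEROPS:M24
    - MEROPS:M28
    - MEROPS:M38
    - MEROPS:M42
    - MEROPS:S09
    - MEROPS:S10
    - MEROPS:S33

# Family lists behind the Table-3-style substrate listing rules.
amylase_families:
  - CAZY:GH13
  - CAZY:GH57
  - CAZY:GH119
exopeptidase_families:
  - MEROPS:M01
  - MEROPS:M14
  - MEROPS:M17
  - MEROPS:M20
  - MEROPS:M24
  - MEROPS:M28
  - MEROPS:M38
  - MEROPS:M42
  - MEROPS:S09
  - MEROPS:S10
  - MEROPS:S33
beta_glucosidase_families:
  - CAZY:GH1
  - CAZY:GH3

# Strict-inequality thresholds: a substrate is listed when the copy total
# exceeds the cutoff.
thresholds:
  amylase_min: 5
  exopeptidase_min: 10
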