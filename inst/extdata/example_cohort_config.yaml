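# Example generator configuration: a two-year pilot cohort at reduced daily
# volume. The late-November 1994 implant is proportionally stronger than the
# study-scale default so it stays detectable at this volume.
start: 1994-03-01
end: 1996-03-01
daily_conceptions:
  "1994": 200
  "1995": 210
  "1996": 215
baseline_case_prob:
  "1994": 0.0015
  "1995": 0.0021
  "1996": 0.0024
clusters:
  - start: 1994-11-07
    end: 1994-12-02
    case_prob: 0.006
sibling_fraction: 0.3
strata_probs:
  metro: 0.8
  south: 0.67
seed: 7
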