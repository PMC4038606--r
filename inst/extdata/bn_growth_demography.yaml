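# Bottleneck + recent 100-fold growth history (sizes in diploid individuals,
# durations in generations; oldest epoch first, last epoch ends at sampling).
# Note: quote the "N" key -- bare N is a YAML 1.1 boolean.
label: BN_growth_example
burn_in: 199999
rescale_lambda: 10
epochs:
  - "N": 10000
    duration: 1
  - "N": 1000
    duration: 40
  - "N": 10000
    duration: 1880
  - "N": 1000000
    duration: 80
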