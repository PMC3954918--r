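# Transfected-tumor dose study: four IL-27 production cases
command: simulate
seed: 1
parameters: defaults
grid: {"R": 0.5, "N": 200}
horizon: 15
snapshot_days: [3, 9, 15]
mu1_values: {none: 0.0, small: 2.0e-6, moderate: 5.0e-6, large: 1.0e-5}
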