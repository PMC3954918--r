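# One-month treatment variant: 4 weeks of drug within a 6-week horizon
command: compare-protocols
seed: 1
parameters: defaults
grid: {"R": 1.2, "N": 96}
horizon: 42
T0: 1.0e+8
epsilon: 0.1
protocol:
  q1: [5000]
  t_end_treatment: 28
  decay_gamma: 1
  on_period: 14
  off_period: 14
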