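# Continuous vs intermittent IL-27 injection, 18-week treatment, 30-week horizon
command: compare-protocols
seed: 1
parameters: defaults
grid: {"R": 1.2, "N": 96}
horizon: 210
T0: 1.0e+8
epsilon: 0.1
protocol:
  q1: [2000, 5000, 10000]
  t_end_treatment: 126
  decay_gamma: 1
  on_period: 21
  off_period: 21
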