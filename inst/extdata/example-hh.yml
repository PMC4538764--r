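# Analytic minimum-cluster search: continuous outcome, within-variance
# input, zero ICC, 6 measurement times, 20 subjects per cluster-period.
method: hh
model:
  family: continuous
  effect: -0.3785
  sd: 1.55
  icc: 0.0
  mode: within
design:
  n_times: 6
  cluster_size: 20
engine:
  target_power: 0.8
  alpha: 0.05
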