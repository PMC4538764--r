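# Simulation-based minimum-cluster search (Monte Carlo, S trials per
# candidate size). Binary outcome specified by baseline risk + odds ratio.
method: search
model:
  family: binary
  p0: 0.26
  odds_ratio: 0.56
  icc: 0.1
  mode: within
design:
  n_times: 6
  cluster_size: 20
engine:
  S: 1000
  seed: 42
  threshold: 0.8
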