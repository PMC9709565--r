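# one model instance: all keys optional, defaults are the baseline conditions
T: 20
q: 0.55
prior_p0: 0.5
fitness:
  shape: convex
  alpha: 2
N: 200
true_env: E0
seed: 42
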