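# Example run configuration for inst/scripts/rvbench.R.
# Omitted fields fall back to the defaults documented in ?readRunConfig
# (seven packaged gene profiles, R = 250, B = 1000, alpha = 0.05,
# n = 1998, the full effect x causal-fraction grid).
replicates: 50
permutations: 500
alpha: 0.05
trait_type: continuous
scenarios: [1, 2, 4]
methods: [T1, T5, WE, VT, WOD1, WOD5, SKAT]
n_individuals: 1998
seed: 1
output_dir: results
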