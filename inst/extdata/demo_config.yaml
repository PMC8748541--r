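# Demonstration configuration: a small fully simulated screen.
seed: 7
out_dir: "dropscan_demo"
simulate: true
replicates: 2
# library sized so substitutions recur across variants (identifiability)
library:
  n_variants: 1000
  mean_nt_mutations: 4.5
  n_codons: 40
screen:
  prior_pi: 0.25
  n_droplets: 20000
sequencing:
  depth: 8000
  error_rate: 0.001
pipeline:
  min_read_quality: 30
  min_mutation_count: 10
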