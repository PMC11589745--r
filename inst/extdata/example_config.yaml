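# aggdev pipeline configuration (synthetic end-to-end run)
seed: 42
out_dir: aggdev-run
n_genes: 200
hgt_fraction: 0.5
support_mean: 100
support_spread: 0
nb_dispersion: 0.05
recipient: Excavata
support_min: 60
de_min: 0.9
rpkm_floor: 10
aggspec_de: 1.0
credibility: 0.99
e_screen: 1.0e-10
e_tree: 1.0e-35
min_euk_groups: 3
library_sizes:
  gro: 5000000
  agg: 5000000
  germ: 5000000
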