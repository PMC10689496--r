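# Minimal pipeline configuration: simulate a small world, run a short
# tip-dated chain and the PCA stage. See ?validate_config for all fields.
seed: 7
out_dir: demo_out
stages: [simulate, phylo, pca]
simulate:
  sim:
    cognates: {n_concepts: 25}
    climate: {n_time_slices: 2, grid_rows: 16, grid_cols: 16}
    pollen: {n_sites: 120}
    cultures: {n_sites: 80}
    genotypes: {n_modern_per_pop: 30, n_ancient: 12, n_snps: 400}
phylo:
  generations: 20000
  thin: 100
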