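# Example splicesel pipeline configuration.
# Run with:  Rscript inst/scripts/splice-cis.R run --config pipeline_example.yaml --out out/
seed: 1
simulate:
  n_genes: 100
trends:
  subsample_size: 2000
  repetitions: 20
constraint:
  n_bins: 20
  pseudo_reps: 50
intragene:
  span: 0.75
popgen:
  theta: 0.005
  n: 10
  L: 50000
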