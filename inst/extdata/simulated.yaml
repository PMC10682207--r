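# Simulated-arm pipeline: regenerate the full-factorial 2100-spectrum canopy
# dataset and run the nine-model estimation experiment.
dataset: simulated
target: cab
seed: 1
grid:
  cab: [25, 50, 5]
  n_structure: [1, 1.5, 0.5]
  lai: [1, 7, 1]
  soil_scale: [0.6, 1, 0.1]
  ala: [0, 60, 15]
split:
  counts: [1569, 531]
selection:
  folds: 10
  nlambda: 100
svr:
  k_folds: 5
outdir: lcc-simulated-run
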