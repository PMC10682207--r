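# Synthetic field-campaign arm: 69 trees with truncated-normal SPAD
# (mean 36.00, sd 2.69, range 29.50-42.00), replicate-averaged measurement
# noise, SPAD as the modeling target.
dataset: field
target: spad
seed: 1
field:
  n: 69
  multiplicative_sd: 0.02
  additive_sd: 0.002
  replicates: 5
split:
  fraction: 0.75
selection:
  folds: 10
svr:
  k_folds: 5
outdir: lcc-field-run
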