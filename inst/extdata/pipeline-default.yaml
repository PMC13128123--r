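# Default pipeline configuration (synthetic mode).
#
# Every field shown here is optional; omitted fields fall back to these
# values. Pass the file to runPipeline() or the drpaudit.R script with
# --config.

# "synthetic" generates a mechanism-structured panel with known ground
# truth; "real" reads the delimited tables named under `paths`.
mode: synthetic

# Overrides for simConfig(): the synthetic panel generator.
sim:
  n_mechanisms: 6          # mechanism classes M
  drugs_per_mechanism: 5   # 30 drugs total
  n_cells: 150             # cell lines
  n_cell_features: 200     # observed noisy features per cell
  fingerprint_width: 256   # bits per drug fingerprint
  p_on: 0.1                # template bit density
  flip_rate: 0.05          # per-bit flip rate within a mechanism
  sigma2_mech: 1.0         # variance of mechanism response means
  sigma2_drug: 0.5         # variance of per-drug mean offsets
  b0: 0.6                  # mean mechanism sensitivity slope
  sigma2_beta: 0.05        # variance of mechanism slopes
  sigma2_slope: 0.05       # variance of per-drug slope offsets
  sigma2_noise: 0.2        # residual response variance
  sigma2_feat: 0.05        # cell feature noise
  pairing_density: 1.0     # fraction of cell x drug pairs measured
  confusable_pairs: []     # e.g. [["M5", "M6"]] for an opposed pair

# Overrides for modelConfigSynthetic(): the two-arm MLP.
model:
  learning_rate: 1.0e-3
  batch_size: 32
  max_epochs: 60
  patience: 6

# Overrides for metaConfig(): the composition elastic net.
meta:
  alpha: 0.01              # penalty strength
  l1_ratio: 0.1            # L1/L2 mixing
  folds: 10

permute:
  replicates: 3

diversity:
  k_grid: [10, 40, 120]    # training cells-per-drug caps
  modes: [mixed]
  replicates: 3

sweep:
  design: partial_blind    # or fixed_test
  n_runs: 150

mechanism:
  mechanisms: null         # null = every target with >= 2 drugs

# Real mode only: input tables (delimited text).
# paths:
#   response: response.csv        # columns cell_line, drug, value
#   expression: expression.csv    # cell_id + gene columns
#   smiles: smiles.csv            # drug_id, smiles
#   annotations: annotations.csv  # drug_id, putative_target, pathway
#   reference_genes: genes.txt    # optional, one symbol per line
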