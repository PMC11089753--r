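# distaff

Protein–ligand binding-affinity prediction from interaction-typed
distance maps, in R.

## The problem

In structure-based drug discovery, the binding affinity of a docked
protein–ligand complex — quantified as pKd = −log10(Kd), higher meaning
tighter binding — is the score that ranks candidate ligands against a
target. `distaff` implements an affinity regressor whose central idea is
to represent the binding pocket by the *distances between atoms that can
actually interact*, rather than by voxel grids or adjacency graphs:

* **donor–acceptor**: hydrogen-bond donor atoms on protein side chains
  (e.g. LYS NZ, SER OG) paired with acceptor N/O atoms of the ligand,
  with no distance cutoff (all ligand heavy atoms are used when a ligand
  has no N/O);
* **hydrophobic**: apolar carbon–carbon pairs closer than 4.5 Å;
* **π-stacking**: aromatic-atom pairs closer than 4.0 Å.

Each distance d_ij is discretized into 40 half-Ångström bins over
[0, 20) Å plus a 41st overflow bin, and the three binned matrices are
flattened and concatenated into a fixed 1000-code pocket vector.
Alongside it, the model uses a 500 × 58 sequence-feature matrix for the
residues that carry interaction-capable side chains (21 one-hot + 30
HMM-profile columns transformed by f = 2^(−0.001·p) + 7 physicochemical
descriptors) and a character-level integer encoding of the ligand SMILES
(150 codes from a 64-character vocabulary).

The three blocks feed a three-branch 1D CNN (filters 32/64/128, lengths
4/8/12; 4/6/8 for SMILES; 128-dim embeddings) whose outputs are
concatenated to a 384-vector, weighted by scaled dot-product attention
(softmax(QKᵀ/√d_k)·V), and regressed through 256- and 128-node FC layers
to pKd. Training uses the log-cosh loss, Adam (lr 0.001, batch 16), 200
epochs with best-validation checkpointing, and deployment averages five
independently trained models. The network is implemented from scratch in
RcppArmadillo; the evaluation suite (Pearson R, RMSE, MAE,
regression-corrected SD, concordance index, ROC AUC, enrichment factors)
and a synthetic-complex generator with a known ground-truth affinity
function complete the pipeline, so everything is testable offline. See
`vignette("affinity-prediction")` for the model description and design
rationale.

## Worked example

```r
library(distaff)

# a small synthetic study: 300 training + 60 test complexes whose true
# pKd is a linear function of their interaction contact counts
spec  <- synthetic_complex_spec(seed = 42)        # box 20 A, noise sd 0.1
train <- featurize_synthetic(generate_dataset(300, spec))
test  <- featurize_synthetic(
  generate_dataset(60, synthetic_complex_spec(seed = 43)))

cfg <- model_config(seed = 1, epochs = 8)         # short synthetic fit
fit <- train_affinity_model(train, cfg, val_fraction = 0.1)
fit
#> <trained_affinity_model> best epoch 4/8, val loss 0.2385

pred <- predict(fit, test)
evaluate_predictions(data.frame(y_act = test$pkd, y_pred = pred))
#> Affinity prediction metrics (n = 60):
#>   R 0.969 | RMSE 0.809 | MAE 0.633 | SD 0.735 | CI 0.928
```

The printed numbers say: across the 60 held-out complexes the predicted
pKd correlates with the truth at R = 0.97 with an RMSE of 0.8 pKd units;
SD is the residual spread after the best linear rescaling of the
predictions, and CI = 0.93 means 93% of comparable pairs are ranked in
the right order. A five-model ensemble (`train_ensemble()`,
`ensemble_predict()`) tightens these further; on the package's full
synthetic study (2000 training complexes) the ensemble reaches held-out
R ≈ 0.99 — by design, since the generator's affinity is an exact
function of the encoded contacts.

Real structures enter through the same surface:

```r
prot <- read_protein("complex.pdb")               # or a pocket .mol2
lig  <- read_ligand("ligand.sdf", smiles = "CCO") # SMILES given directly
hhm  <- parse_hhm("protein.hhm")                  # precomputed profile
f    <- featurize_complex(prot, lig, hhm = hhm)
predict(fit, f)
```

A thin command-line wrapper (`inst/scripts/distaff`) chains the same
steps: `simulate`, `featurize`, `train`, `predict`, `evaluate`,
`screen`; every run writes a `run_info.json` provenance record.

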