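# dtakit

Drug–target binding affinity (DTA) regression in R, for computational
chemists and bioinformaticians who want a fully inspectable,
dependency-light implementation of the word-frequency/graph-network DTA
approach: no deep-learning framework, every layer and gradient written
out and tested.

## What it implements

**Protein encoding.** A protein over the 25-letter residue alphabet
(20 standard amino acids + B, O, U, X, Z) is encoded as a
word-frequency-weighted polypeptide frequency vector. For peptide order
*n*, with *p<sub>i</sub>* occurrences of peptide *i* in a sequence of
length *L*, *w<sub>i</sub>* the number of corpus sequences containing
peptide *i*, and *N* the corpus size:

```
wf_i = (w_i / N) · p_i / (L − n + 1),        i = 1 … 25^n
```

Dipeptides (625 features) are the default; orders 1 and 3 give 25 and
15,625 features. The corpus weight deliberately *up*-weights common
peptides — the inverse-document-frequency weighting of text processing
(`idf()`, provided for comparison) suppresses exactly the features that
carry signal in sequences.

**Drug graphs.** SMILES compounds become molecular graphs: heavy atoms
as nodes with 78-dimensional feature vectors (element one-hot over 44
buckets; atomic rank, hydrogen count and implicit valence one-hot over
0–10; an aromaticity bit), chemical bonds as directed edge pairs.

**Four hybrid architectures.** A drug branch — `gcn` (channels
78/156/312 + FC 1024), `gin` (five 32-wide isomorphism units), `gat`
(78×10-head then 128×1-head attention) or `gat_gcn` (attention into a
780-channel convolution + FC 1500) — meets a protein branch (32
width-8 conv filters over the encoding) in 128-dimensional embeddings,
concatenated through 512- and 128-unit layers to a scalar affinity.
Training is Adam on MSE, fully seeded; gradients are hand-derived and
verified against finite differences in the test suite.

**Evaluation & analysis.** Concordance index (checked against a
brute-force pair enumeration), MSE, Pearson correlation; random-forest
variable importance over dipeptide features (normalized, ranked at a
0.5% contribution threshold, 25×25 grid layout); affinity data loaders
for long CSV and dense matrix formats, the pKd transform
`−log10(Kd/1e9)`, the ≥10-interactions filter, seeded 80/20 splits; a
seeded synthetic benchmark generator with a planted, documented signal.

## Worked example

```r
library(dtakit)

spec <- synthetic_spec(seed = 42)        # 20 proteins x 10 drugs, planted "PE"
ds <- simulate_dataset(spec)
ds
#> <affinity_dataset> 200 records (10 drugs x 20 proteins), units = pKd

split <- train_test_split(ds, 0.8, seed = 42)
train_feats <- featurize_pairs(split$train, n = 2)   # weights fit on train only
test_feats  <- featurize_pairs(split$test, weights = train_feats$weights)

cfg <- model_config("gat_gcn", protein_input_dim = 625,
                    batch_size = 32, learning_rate = 1e-3,
                    epochs = 30, seed = 42)
model <- train_dta(build_model(cfg), train_feats)
report <- evaluate_predictions(test_feats$affinity,
                               predict_dta(model, test_feats))
report
#> <metrics_report> n = 40
#>   MSE     = 0.013310
#>   CI      = 0.696154
#>   Pearson = 0.824965
```

The held-out MSE (0.013) sits well below the label variance of the
planted model (0.039 for this panel): the network has learned most
of the planted protein/drug structure from 160 pairs in 30 epochs. The
CI of 0.70 says 70% of strictly ordered test pairs are ranked
correctly — on a panel whose noise floor keeps perfect ranking out of
reach.

The importance analysis recovers the planted dipeptide:

```r
enc <- encode_corpus(protein_set(unique(ds$sequence),
                                 unique(ds$protein_id)), n = 2)
vim <- compute_vim(enc[ds$protein_id, ], ds$affinity,
                   n_trees = 2000, seed = 42)
vim
#> <vim_report> 625 features, 625 with non-zero importance (2000 trees, impurity)
#>   top: PE (5.9%), YC (3.7%), PL (3.3%), LO (3.1%), FG (2.7%)
```

"PE" (proline–glutamate) is the dipeptide the generator planted; its
importance share is what separates it from the 624 noise features.

## Command line

The installed script `exec/dtakit` wires the same pipeline into
subcommands:

```sh
dtakit simulate --output panel.csv --seed 1
dtakit encode   --input proteins.fasta --output encoded.csv --n 2
dtakit train    --input panel.csv --output run/ --branch gat_gcn --epochs 30 --seed 1
dtakit eval     --model run/checkpoint.rds --input panel.csv --output eval/
dtakit vim      --input panel.csv --output vim/ --trees 10000 --seed 1
```

Outputs (checkpoint, loss history, metrics, predictions, importance
tables) are stamped with the configuration and seed; reruns with the
same seed are byte-identical.

## Scope

Desk-scale by design: the synthetic benchmark exercises every code path
at real dimensionality, but reproducing published benchmark figures on
KIBA/Davis requires the external downloads and long training runs that
are out of scope here. See the vignette
(`vignettes/word-frequency-graph-dta.Rmd`) for the model details,
numerical choices and limitations.
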