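# lncloc

Sequence-based prediction of long non-coding RNA (lncRNA) subcellular
localization: nuclear versus cytosolic.

## The problem

Most human lncRNAs are unannotated, and where a transcript accumulates in
the cell — chromatin/nucleus or cytosol — is one of the strongest single
clues to its function. Fractionation RNA-seq (sequencing nucleus and
cytosol separately) measures localization directly, but only for the cell
types assayed. `lncloc` is for transcriptomics researchers who want to
(a) derive nuclear/cytosolic labels from fractionation experiments and
(b) train a classifier that predicts localization for *any* lncRNA from
its cDNA sequence alone.

## The method

**Labels.** For each cell type, a differential-expression table gives each
transcript a nuclear:cytosolic log2 fold-change `l2fc`. Per transcript,
tables are aggregated by a sample-size weighted average over the cell
types in which it was detected:

    l2fc_agg = Σ_c n_c · l2fc_c / Σ_c n_c

Because lncRNAs are nuclear-skewed overall (every transcript starts in the
nucleus), symmetric cutoffs are inappropriate; cutoffs are placed at the
first and third quartiles of the aggregated distribution, with strict
inequalities: cytosolic if `l2fc_agg < t_lo`, nuclear if `l2fc_agg >
t_hi`, otherwise unlabeled. Labeled transcripts are split 70/15/15 into
train/validation/test.

**Features** (per transcript, from sequence + annotation):

- k-mer spectrum: relative frequency of every k-mer for k = 2..5
  (4² + 4³ + 4⁴ + 4⁵ = **1360 features**), each k-block normalized by its
  number of valid (N-free) windows;
- RNA-binding-protein motif counts: each PWM is scored in sliding windows
  by its summed log-odds `log2((p_ib + c·b_b)/((1+c)·b_b))` against a
  uniform background with pseudocount `c`; a window counts as a match when
  its score strictly exceeds 80% of the maximal attainable PWM score;
- genomic context: one-hot lncRNA biotype (lincRNA/intergenic, antisense,
  sense intronic, sense overlapping, other) with a derived
  "sense-proximal" flag, and one-hot chromosome (1–22, X, Y, MT, other).

**Model.** A feed-forward neural network: three ReLU hidden layers
(default 128-128-64), softmax output over {nuclear, cytosolic}, inverted
dropout on inputs (0.1) and hidden activations (0.5), L1/L2 weight
penalties, trained by mini-batch SGD with momentum and early stopping on
validation misclassification. Features are standardized with training-set
statistics only. Hyperparameters can be tuned by random search on
validation misclassification (`random_search()`, shipped space in
`inst/extdata/search_space.yaml`).

**Evaluation.** Accuracy, sensitivity, specificity, F1 and MCC from the
confusion matrix (positive class = nuclear), plus the cutoff-swept ROC
curve with trapezoidal AUC (equal to the Mann–Whitney concordance
probability, ties at half credit).

A synthetic-data generator produces transcripts with a planted
nuclear-retention motif (default the AGCCC pentamer) at class-specific
Poisson rates, matching annotations, and noisy per-cell-type fold-change
tables, so the entire pipeline is testable without any external data.

## Worked example

```r
library(lncloc)

spec <- synthetic_spec(n_per_class = 500, seed = 7)   # planted AGCCC, rate 3 vs 0
tx   <- generate_transcripts(spec)
pwms <- generate_fixture_pwms(c("AGCCC", "GAATTC", "TTAGGG"))
rec  <- transcript_records(tx$sequences, tx$annotation)
fm   <- assemble_feature_matrix(rec, pwms = pwms)     # 1000 x 1395 features

y  <- setNames(tx$truth$class, tx$truth$transcript_id)
sp <- split_dataset(rownames(fm), seed = 7, stratify_by = y[rownames(fm)])
fit <- dnn_localizer(fm[sp$train, ], y[sp$train],
                     fm[sp$val, ],   y[sp$val], config = dnn_config(seed = 7))
fit
#> Feed-forward lncRNA localization network
#>   inputs  : 1395 features (registry 4e38e7ba)
#>   hidden  : 128-128-64 (ReLU)
#>   output  : softmax over nuclear/cytosolic
#>   trained : 100 epochs on 700 rows; best epoch 83 (val misclass 0.1200)

evaluate_predictions(predict(fit, fm[sp$test, ]), y[sp$test])
#> Classification metrics (positive class: nuclear)
#>   TP 60  TN 66  FP 9  FN 15
#>   accuracy     0.8400
#>   sensitivity  0.8000
#>   specificity  0.8800
#>   f1           0.8333
#>   mcc          0.6822
#>   auc          0.9172
```

The 1395 columns are the 1360 k-mer frequencies, 3 motif-count columns,
the 6-column biotype block and the 26-column chromosome block. An
accuracy of 0.84 with AUC 0.92 on the held-out test set means the network
recovers most of the planted localization signal; the residual error is
dominated by nuclear transcripts that happened to receive 0–1 motif
insertions (Poisson sampling) and are genuinely indistinguishable from
background.

A command-line wrapper with `simulate | featurize | label | split | train
| search | predict | evaluate | report` subcommands (each writing a JSON
run manifest next to its outputs) ships at:

```sh
Rscript $(Rscript -e 'cat(system.file("cli", "lncloc.R", package = "lncloc"))') simulate --out bundle/ --n-per-class 100 --seed 4
```

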