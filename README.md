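# ptmscan

Prediction of post-translational modification (PTM) sites in protein
sequences from sequence information alone.

Enzymes that phosphorylate, acetylate or hydroxylate proteins recognize
short sequence contexts around the modified residue. `ptmscan` screens
query proteins for such contexts: every protein is dissected into
overlapping 9-residue windows, each residue is described by ten
physicochemical AAindex property scales — so a window becomes a point
in a 90-dimensional feature space — and a per-PTM-type multilayer
perceptron (90 sigmoid input neurons, one hidden layer, 2 output
neurons) classifies the window. The package is aimed at computational
biologists who need high-throughput site screening for whole proteomes
and at method developers who want a fully reproducible, testable
implementation of this classical architecture.

Training minimizes the sum of squared errors by per-sample
back-propagation with momentum,

    dw(t) = -eta * dE/dw + delta * dw(t-1),    eta = delta = 0.8,

on class-ratio-controlled random sub-sampling splits (positives 4:1
train:test, negatives 1:5 per positive, three random splits). The
hidden-layer width is swept over 2..20 in steps of 2, and within every
run the weights maximizing the selection criterion on the held-out test
split are checkpointed. Three networks are trained per PTM type —
optimized for AUC, recall and precision respectively — and each
prediction carries a confidence `C_j = R_j / sum(R)`, the normalized
response of the winning output neuron. Performance is summarized by the
classification error, recall/sensitivity, precision, TPR/FPR,
specificity, accuracy, MCC, ROC curves and the Mann–Whitney AUC.

## Worked example

Train an AUC-optimized network on a synthetic PKA-like motif dataset
(consensus context `KRRASFAAA`, phospho-acceptor serine at the center,
90% consensus strength) and scan a protein:

```r
library(ptmscan)

motif <- motif_spec(consensus = "KRRASFAAA", consensus_strength = 0.9)
ds <- generate_dataset(motif, n_pos = 100, neg_per_pos = 5, seed = 1,
                       ptm_type = "Phospho/PKA")
#> <labeled_dataset> Phospho/PKA - 100 positives, 500 negatives

sp  <- split_dataset(ds, split_spec(n_splits = 1, seed = 1))[[1]]
fit <- sweep_hidden(sp$train, sp$test, h_values = c(2, 4, 8),
                    config = train_config(epochs = 60, seed = 1),
                    criterion = "auc")
fit$report
#>   hidden value best_epoch
#> 1      2     1          1
#> 2      4     1          6
#> 3      8     1          2
```

All three hidden sizes reach test AUC 1 on this strongly separable
toy; the tie goes to the smallest network (90-2-2). Scanning a protein
containing one planted motif instance:

```r
w    <- generate_windows("MDKRRASFAAAYLCLYTHIGR")
pred <- predict_windows(w$segment, fit$model)
writeLines(format_predictions(pred))
#> MDKRRASFA 0 0.9879
#> DKRRASFAA 0 0.9237
#> KRRASFAAA 1 0.8630
#> RRASFAAAY 0 0.9510
#> RASFAAAYL 0 0.9822
#> ...
```

Each line is `SEGMENT DECISION CONFIDENCE`: 1 flags a predicted
modification site at the window center, 0 a negative, and the third
column is the winning class's normalized-response confidence — the
planted motif window is called positive with confidence 0.8630, every
off-center or background window is confidently rejected. The same
pipeline is available from the shell:

```sh
Rscript $(Rscript -e 'cat(system.file("cli/ams3.R", package="ptmscan"))') \
    generate --fasta proteome.fa --out windows.txt
Rscript ... predict --windows windows.txt --models models/ \
    --ptm-type Phospho/PKA --optimization auc --out predictions.txt
```

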