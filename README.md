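# cmfusion

Cross-modal fusion of medical images and laboratory time series with
dynamic feature pruning, in pure R.

Clinical classification increasingly pairs an imaging study (chest
radiograph, dermoscopy) with a short panel of laboratory time series — `K`
indicators measured at `T` successive draws. The two modalities are
heterogeneous, and their naive concatenation is redundant and semantically
misaligned. `cmfusion` implements, end to end and trainable on one CPU:

* a **patch-token transformer** image encoder (class token + position
  embeddings, pre-norm blocks) and a **per-time-step MLP** laboratory
  encoder with temporal mean pooling, both mapping into a shared
  d-dimensional space;
* the **SmartTrim gate**: sigmoid importance scores on the concatenated
  feature `F_cat = [F_I; F_L]`, an adaptive threshold
  `τ = mean(S) + λ·std(S)` (population std, λ = 0.3 by default), an
  inclusive binary mask with an empty-mask guard, and elementwise gating
  `F_prune = F_cat ⊙ M`;
* **cross-modal attention fusion**: queries from the gated image branch,
  keys/values from the laboratory branch,
  `softmax(QKᵀ/√d)·V`, residual-connected to the image branch and layer
  normalized, then a bottleneck prediction head;
* the **three-term objective**
  `L = L_cls + α·(1 − cos(F_I, F_L)) + β·mean(M)` (α = 0.1, β = 0.05),
  trained with AdamW, 5-epoch warmup + cosine annealing (1e-4 → 1e-6),
  and early stopping on validation macro F1 (patience 10), with
  straight-through gradients at the hard mask;
* the **metric suite**: accuracy, macro F1, macro one-vs-rest AUC, Cohen's
  kappa, feature sparsity (% exact zeros in the gated feature), cross-modal
  cosine similarity, trainable-parameter and FLOP accounting;
* **experiment protocols**: a seven-row module ablation grid, a λ
  sensitivity sweep, perturbation robustness curves (Gaussian image noise
  and random laboratory masking at intensities 0–40%), and repeated
  stratified k-fold cross-validation;
* a **synthetic paired-data generator** with planted class motifs in both
  modalities, a shared cross-modal latent, and a configurable fraction of
  pure-noise laboratory dimensions, so everything above is exercisable
  without any download.

The methods vignette (`vignettes/cross-modal-fusion.Rmd`) documents the
model, the design decisions and the numerical conventions.

## Worked example

```r
library(cmfusion)

# 600 samples, 4 classes, 32x32x3 images, T = 10, K = 8 (4 dims pure noise)
dataset  <- generate_dataset(preset_strong_signal(seed = 1))
config   <- cmf_config()                 # d = 64, depth 2, 4 heads, λ = 0.3
prepared <- cmf_prepare(dataset, config, seed = 1)

fit    <- cmf_train(prepared, config, train_config(epochs = 30, seed = 1))
report <- cmf_evaluate(fit, prepared$test)
report
```

```
cmf_report (n = 60)
  accuracy  1.0000   f1_macro 1.0000   auc_macro 1.0000   kappa 1.0000
  sparsity  62.1%   cross-modal cos 0.5681
  params    183,108 (0.183 M)   flops 1,487,588 (0.0015 G)
  loss      total 0.5270 = cls 0.4643 + a*cm 0.4319 + b*sparse 0.3905
```

The planted class signal is strong, so the trained toy model classifies the
held-out split perfectly; the gate zeroes 62% of the 128 concatenated
feature dimensions (the lab encoder's outer ReLU alone accounts for
~15–20% of exact zeros); the alignment term has pulled the mean cosine
between the two modality embeddings to 0.57; and the loss line decomposes
the objective into its three components (`a`, `b` are the α, β weights).

One sample can be inspected at every stage:

```r
state <- forward_full(list(image = prepared$test$images[[1]],
                           lab   = prepared$test$labs[[1]]), fit$model)
state$pruning$tau
#> [1] 0.4995
state$pruning$mask[1:8]
#> [1] 0 1 0 1 0 1 0 0
```

Protocol runners return plain data frames:

```r
run_ablation(dataset, config, train_config(epochs = 8), seeds = 1:3)$table
sweep_lambda(dataset, config, train_config(epochs = 8), seeds = 1:3)
run_robustness(fit, prepared)        # accuracy vs perturbation level
cross_validate(dataset, config, k = 5, n_repeats = 3)$summary
```

A thin command-line wrapper over the same functions is installed at
`inst/cli/cmfusion.R`:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli/cmfusion.R", package="cmfusion"))')" \
    train --seed 1 --out runs/demo
```

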