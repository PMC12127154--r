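# causalecg

Multi-label ECG classification with a backdoor-adjusted, attention-based
causal head — plus a synthetic generator of *confounded* ECG populations so
the causal claims can be exercised end to end without external data.

## The problem and the model

ECG classifiers learn shortcuts: recording-level nuisance processes
(baseline wander, lead gain, noise, patient physiology) influence both the
waveform X and, through dataset composition, the label Z. The spurious
association travels the backdoor path X ← C → Z, and a model that exploits
it fails as soon as the co-occurrence pattern shifts.

`causalecg` targets the interventional distribution instead of the
observational one:

    P(Z | do(X)) = Σ_c P(Z | X, c) P(c)

The confounder set C is represented by a **confounder dictionary** of
per-class average feature vectors f_d(c) with empirical priors P(c).
Because softmax heads satisfy the normalized-weighted-geometric-mean (NWGM)
identity

    NWGM[f] = Softmax(E_x[g(x)]),

the backdoor sum collapses to a single forward pass with the expected
confounder: `P(Z|do(X)) ≈ Softmax(g(X, E_c[c]))`.

The network: a 12-lead recording is split into six lead-pair **views**
encoded by a shared 1-D conv stack; per-view maps are averaged and embedded
at two time scales by the dual-kernel **TDFE** module (kernels 5 and 50);
each scale's feature queries the dictionary through scaled dot-product
**attention fusion** (keys/values are learned affine projections of the
dictionary); the token triple [f; fused; E_c[c]] passes through one
transformer encoder block and an MLP into the interventional head. Training
uses the two-branch loss `L = α1·L_ce1 + α2·L_ce2` with Adam, cosine
annealing, batch size 64 and a per-epoch dictionary refresh. The default
network has ~118k trainable parameters (budget: ≤ 0.25 M).

## Worked example

```r
library(causalecg)

## a confounded population: K = 4 classes, 12 leads, 10 s at 100 Hz;
## confounder intensity correlates with class 1 at rho = 0.8
sc  <- synth_config()
tr  <- generate_dataset(sc, 240, rho = 0.8, seed = 1)
va  <- generate_dataset(sc, 60,  rho = 0.8, seed = 2)

cfg <- model_config()
count_parameters(init_model(cfg, seed = 1))
#> [1] 118064

fit <- train_model(list(train = tr$records, val = va$records), cfg,
                   train_config(epochs = 10, seed = 1), verbose = TRUE)
#> epoch  1  lr 1.00e-03  train 2.0745  val 1.3990  val_auc 0.8799
#> ...
#> epoch 10  lr 0.00e+00  train 0.9770  val 1.0018  val_auc 0.9584

te <- generate_dataset(sc, 60, rho = 0.8, seed = 3)
scores <- predict_model(fit$state, te$records)
y <- do.call(rbind, lapply(te$records, `[[`, "labels"))
compute_metrics(scores, y)
#> macro-AUC 96.96%  SEN 17.99%  F1 23.14%  recall 17.99%  acc 79.17%  mAP 94.32% (threshold 0.50, 0 class(es) excluded from AUC)
```

`macro-AUC` is the class-averaged rank AUC (midrank ties), `SEN` the macro
recall at threshold 0.5, `mAP` the macro average precision. The numbers are
from this 10-epoch desk-scale run (seeds as shown): ranking metrics are
already strong while the softmax scores are still under-confident at the
fixed 0.5 threshold, which is why SEN/F1 lag the AUC; training at the
default scale (n = 1000, more epochs) saturates the in-distribution task.

Robustness to confounder shift — evaluate the frozen model on populations
whose label–confounder correlation is reversed:

```r
shift_protocol(fit$state, sc, rho_train = 0.8, rho_test_list = -0.8,
               n_test = 60, seed = 9)
#> ... drop[["macro_auc"]] = 0.5415
```

The returned report gives in-distribution metrics, shifted metrics, and
their difference per metric; the large macro-AUC drop printed above
quantifies how much this model leans on the spurious association at
rho = 0.8.

## Command line

A thin CLI over the same functions ships in `inst/cli/causalecg`:

```sh
inst/cli/causalecg simulate --n 200 --rho-train 0.8 --rho-test -0.8 --seed 1 --out data/
inst/cli/causalecg train    --data data/train --epochs 10 --seed 1 --out model/
inst/cli/causalecg evaluate --checkpoint model/checkpoint.rds --data data/test --out eval/
inst/cli/causalecg shift-bench --checkpoint model/checkpoint.rds \
    --manifest data/train/manifest.json --rho-test -0.8,0 --seeds 1,2,3 --out shift.csv
inst/cli/causalecg ablate   --data data/train --seed 1 --out ablation.csv
```

Datasets are directories of per-record `.npy` files plus `labels.csv` and a
JSON manifest; recordings can also be read from CSV (samples × leads) and
WFDB format-16 record pairs.

## Acceptance script

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

re-runs the main computation from scratch: it generates the default
confounded population, reports the assembled network's parameter count,
trains the full model, evaluates multi-label metrics on a held-out test
set, measures the reversed-shift macro-AUC drop, and writes the JSON
report to `--out`.

## Package layout

- `R/` — recording IO and views, the synthetic generator, conv/TDFE
  encoder, dictionary + NWGM causal head, training loop, metrics and the
  shift protocol, CLI dispatcher
- `src/` — compiled 1-D convolution and fused-encoder kernels
- `vignettes/causal-ecg-methods.Rmd` — the model, assumptions, parameter
  choices, generator design and limitations
- `tests/testthat/` — unit, property and acceptance suites
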