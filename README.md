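# ildfusion

Attention-weighted multimodal fusion for interstitial lung disease (ILD)
classification, with a synthetic cohort generator and a modality-ablation
harness.

## What this package is for

Diagnosing ILD draws on three very different data streams per patient: chest
CT imaging (fibrotic "honeycomb" texture in the lung periphery),
physiological time series (arterial oxygen tension, PaO2, typically ~85 mmHg
in cases vs ~95 mmHg in controls), and the clinical narrative (dyspnea,
cough, crackles). `ildfusion` implements, from first principles in R (with
small compiled kernels for the convolution hot loops), a classifier that
encodes each stream separately and fuses them with an attention mechanism:

* **image encoder** — blocks of valid cross-correlation + ReLU + 2×2 max
  pooling, global average pooling, linear map to a common width d_model;
* **series encoder** — a bidirectional LSTM (standard input/forget/output
  gate equations), directions merged by elementwise sum, temporal mean
  pooling;
* **text encoder** — token embeddings + sinusoidal positional encoding and
  one multi-head self-attention block
  (E_ij = Q_i·K_j / √d_k, row-softmax weights, per-head outputs
  concatenated and mixed by W_O);
* **fusion head** — projected modality tokens α_m = tanh(W_m H_m) are mixed
  by cross-modality self-attention into tokens β_m, scored by a learned
  vector (E_m = s·β_m), softmax-normalised into simplex fusion weights w,
  and combined as M = Σ_m w_m β_m before a softmax classifier
  Ŷ = softmax(λM + b).

Training is mini-batch AdamW (decoupled weight decay) on the cross-entropy,
with analytic backpropagation through every layer, verified against central
finite differences. Evaluation reports precision/recall/F1 for the ILD
class, Mann-Whitney AUC (ties counted 1/2), ROC points and the confusion
matrix. The ablation harness retrains the model from scratch for each of
the six studied modality subsets (image; series; image+series; text+series;
text+image; all three) under shared seeds.

Because no clinical cohort ships with the package, a synthetic generator
produces multimodal cohorts with controllable per-modality class signal:
case-dependent peripheral image texture with subject-level severity, a
PaO2-like channel centred at 85/95 mmHg with between-subject scatter, and
class-specific symptom vocabularies. At signal strength 0 the two classes
are distributionally identical; at full strength each single modality
supports an AUC of roughly 0.85–0.95 and the fused model approaches 1.
See `vignettes/multimodal-fusion-methods.Rmd` for the model, the
generator's assumptions, and the design decisions.

## Worked example

```r
library(ildfusion)

# a 2:1 cohort of 150 subjects, full signal strength, stratified 80/20 split
gen <- generator_config(n_cases = 100, n_controls = 50, rng_seed = 7)
cohort <- generate_dataset(gen)

model <- train_model(cohort, model_config(),
                     train_config(epochs = 10, rng_seed = 7))
round(model$loss_history, 3)
#>  [1] 0.667 0.587 0.497 0.371 0.345 0.317 0.297 0.288 0.279 0.272

evaluate_model(model, cohort)
#> metric_report (n = 30)
#>   precision 0.9000  recall 0.9000  F1 0.9000  AUC 0.9250
#>   confusion (rows = truth, cols = prediction):
#>      pred
#> truth 0  1
#>     0 8  2
#>     1 2 18
```

The loss history is the mean training cross-entropy per epoch (nats); it
falls from chance level (ln 2 ≈ 0.693) as the model learns the planted
signal. The report gives the ILD-class precision/recall/F1 at the argmax
threshold, the Mann-Whitney AUC of the predicted P(ILD), and the 2×2
confusion matrix on the held-out test split (here 2 false positives and 2
false negatives among 30 test subjects).

Per-sample prediction exposes the fusion weights — how much each modality
contributed for that subject:

```r
pred <- predict_sample(cohort$samples[[1]], model$params, model$config, model$norm)
round(pred$fusion_weights, 3)
#> [1] 0.327 0.325 0.347
```

The command-line interface wraps the same functions:

```sh
inst/cli/ildfusion simulate --seed 1 --out cohort/
inst/cli/ildfusion train    --data cohort/ --seed 1 --out run/
inst/cli/ildfusion evaluate --data cohort/ --checkpoint run/checkpoint.rds --out eval/
inst/cli/ildfusion ablate   --data cohort/ --seed 1 --out ablation/
inst/cli/ildfusion inspect
```

`inspect` prints the per-layer parameter table and the analytic MAC/FLOP
estimate (1 MAC = 2 FLOPs).

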