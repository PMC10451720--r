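# flockwatch

Video-stream detection of aggressive behavior in group-housed sheep, from
object-detection output to per-second aggression calls.

Aggression in a pen — two sheep colliding head-to-head or head-to-body
with violent locomotor bursts — is a welfare signal that is still mostly
scored by human observation. Given a surveillance camera and an object
detector that emits per-frame bounding boxes `[x, y, w, h]` with
confidence scores, `flockwatch` implements the downstream analysis:

1. **Detection I/O** — read/write YOLO-style per-frame `.txt` files
   (normalized or pixel dialect) and long-format CSV detection streams.
2. **Ordering heuristic** — per frame, discard boxes below the detector's
   operating confidence (0.6), recenter the origin to the image midpoint,
   assign boxes to Cartesian quadrants, sort each quadrant by distance to
   the center, and pack normalized `[x, y, w, h]` 4-tuples into a fixed
   600-dimensional zero-padded vector (4 quadrant blocks × 150 dims).
   This is ordering, not identity tracking: it makes input unit *j* of the
   sequence model tend to see the same animal frame after frame.
3. **Clip tensors** — cut streams into one-second windows and keep one
   frame in two (25 → 12 frames), giving a `12 × 600` matrix per clip,
   min–max normalized to `[0, 1]`.
4. **Classifier** — an LSTM (input/forget/output gates, tanh cell
   candidate) over the packed rows, a fully connected head fusing all
   hidden states into one logit, sigmoid output, binary cross-entropy
   loss, Adam (lr 0.01), deterministic given a seed. Implemented in
   vectorised base R; no deep-learning backend required.
5. **Evaluation** — confusion matrix, precision, recall, F1 (aggression
   positive), ROC by threshold sweep, trapezoidal AUC (exactly the
   Mann–Whitney statistic under ties).
6. **Synthetic flock** — a simulator that emulates pen surveillance at
   the detection level: 10–70 sheep, calm random walks vs. an engaged
   charge–recoil pair, distance-decaying confidence, temporally
   persistent missed detections and ghost boxes. It makes the whole
   pipeline trainable and testable without access to farm video.

In the core formulas: `P = TP/(TP+FP)`, `R = TP/(TP+FN)`,
`F1 = 2PR/(P+R)`; min–max normalization `x' = (x − min x)/(max x − min x)`;
loss `−(1/N) Σ [yᵢ log pᵢ + (1−yᵢ) log(1−pᵢ)]`, whose value for an
uninformative predictor on balanced classes is `ln 2 ≈ 0.693` — the
reference level for the with/without-heuristic ablation.

## Worked example

```r
library(flockwatch)

# Evaluation arithmetic on a published-style test-set confusion matrix
prf <- precision_recall_f1(395, fp = 28, fn = 35, tn = 427)
round(100 * prf$precision, 2)   # 93.38
round(100 * prf$recall, 2)      # 91.86

# One aggressive clip at the camera's native geometry (2560x1440 @ 25 fps)
clip <- simulate_clip(scenario_config(behavior = "aggressive",
                                      n_animals = 25, seed = 11))
tensor <- build_clip_tensor(clip)
dim(tensor)                  # 12 600   (12 kept frames x 600 packed dims)
sum(tensor[1, ] != 0) / 4    # 22       (boxes packed in the first frame:
                             #           25 sheep minus misses/conf filter)

# Train on a small balanced synthetic set and evaluate
clips <- make_dataset(25, 10, seed = 3)
train <- build_clip_set(clips$train)
model <- train_classifier(train, classifier_config(hidden_dim = 32,
                                                   epochs = 50, seed = 3))
glance(model)
#   hidden_dim num_layers fusion            epochs train_loss precision recall
#           32          1 concat_all_steps      50     0.0148         1      1

eval_report(predict_clips(model, train))
# <eval_report> n = 50 clips
# precision 1.0000 | recall 1.0000 | f1 1.0000 | auc 1.0000
```

The final training loss (0.015, far below the uninformative 0.693) and
the perfect in-sample report show the network reading the heuristically
ordered motion pattern; disable the heuristic
(`build_clip_set(..., order = "shuffled")` with
`train_classifier(..., reshuffle_each_epoch = TRUE)`) and the training
loss instead stays pinned near 0.69. `autoplot()` methods draw the
training history, ROC curves, and detection streams; `tidy()`/`glance()`
return the history and summaries as tibbles. See the methods vignette
(`vignettes/flockwatch-methods.Rmd`) for the model, the simulator's
assumptions, and what desk-scale experiments do and do not establish.

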