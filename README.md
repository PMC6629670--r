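# valveweak

Weak supervision for classifying aortic valve malformations — bicuspid
(BAV) vs. tricuspid (TAV) — from phase-contrast cardiac MRI sequences,
implemented end to end in R and testable without any restricted imaging
data.

## The problem and the approach

BAV is the most common congenital heart malformation, but in biobank-scale
MRI collections almost no sequences carry labels, and BAV prevalence is
only ~6 per 100, so hand-labeling enough positives for supervised deep
learning is impractical. Instead of labels, this package uses *data
programming*: domain heuristics vote noisily on unlabeled frames, a
generative model estimates each heuristic's reliability without ground
truth, and a classifier is trained on the resulting probabilistic labels.

The components, in pipeline order:

1. **Phantom cohorts** (`sample_cohort_specs()`, `render_sequence()`) —
   seeded synthetic phase-contrast-like sequences (30 frames, 192×192,
   MAG/CINE/VENC channels) with a planted flow region whose eccentricity
   and boundary irregularity differ by class. Real MRIs are
   access-restricted; the phantoms reproduce the statistical structure the
   pipeline assumes.
2. **Preprocessing** (`preprocess_sequence()`) — the aorta is localized as
   the 32×32 window maximizing per-pixel temporal standard deviation of
   the MAG channel, the peak-flow frame is the frame of maximal spatial
   standard deviation, and all channels are cropped and aligned to a
   ±7-frame window around the peak.
3. **Shape primitives** (`compute_primitives()`) — each frame is
   Otsu-binarized; its largest 8-connected component yields area,
   perimeter, eccentricity, mean intensity, and area/perimeter², all
   normalized by sex-stratified population means of the unlabeled cohort.
4. **Labeling functions** (`make_default_lfs()`, `apply_lfs()`) — five
   threshold heuristics (LF_Area, LF_Perimeter, LF_Eccentricity,
   LF_Intensity, LF_Ratio) vote {−1, 0, +1} = {TAV, abstain, BAV} on a
   6-frame window centered on the peak frame, giving the label matrix
   Λ ∈ {−1, 0, 1}^(m×n).
5. **Generative label model** (`label_model()`) — a factor graph over Λ
   and the latent frame labels y:

       p(Λ, Y) ∝ exp Σᵢ [ θ₀yᵢ + Σⱼ θʲ_Acc yᵢ Λᵢⱼ + Σⱼ θʲ_Lab 1(Λᵢⱼ≠0)
                           + Σ_(j,k) θⱼₖ 1(Λᵢⱼ = Λᵢₖ) ]

   with accuracy, labeling-propensity, shared-primitive dependency
   (`infer_dependencies()`), and class-prior factors, fitted by persistent
   contrastive divergence (SGD with Gibbs-sampled gradient expectations).
   Frame marginals are exact: P(yᵢ=1|Λᵢ) = σ(2Σⱼ θʲ_Acc Λᵢⱼ).
6. **Patient aggregation** (`aggregate_patients()`) — a patient keeps the
   mean of its window marginals if the mean exceeds 0.9, else the minimum
   if the minimum is below 0.5, and is otherwise discarded.
7. **Noise-aware classifier** (`train_classifier()`) — a small
   convolutional frame encoder, a bidirectional recurrent sequence encoder
   with soft attention, and a logistic head, trained with the noise-aware
   loss E_{y~ŷ}[cross-entropy] on the probabilistic labels, with
   validation-based early stopping, threshold tuning
   (`tune_threshold()`), and optional affine augmentation
   (`augment_training_set()`).
8. **Evaluation** (`classification_metrics()`, `ndcg()`,
   `summarize_runs()`) — precision/recall/F1/AUROC plus NDCG
   (DCG = Σ rᵢ/log₂(i+1), normalized by the perfect ranking), summarized
   over seeds with 95% t-intervals.

`scaleup_experiment()` runs the central experiment: on a 1200-patient
phantom cohort at 6% prevalence, weak training sets of growing size
(50/250/1000) are compared against a 100-example hand-labeled baseline
under identical architectures and 5 model seeds.

## Worked example

```r
library(valveweak)

## a small cohort: render, preprocess, weakly label
specs   <- sample_cohort_specs(200, prevalence = 0.06, seed = 42)
aligned <- preprocess_cohort(specs, channels = "MAG")
weak    <- weak_label_cohort(aligned, seed = 1)

summary(weak$model)
table(weak$patient_labels$provenance)
```

```
Label model weights (implied accuracy = logistic(2 * weight)):
                             lf accuracy_weight propensity_weight implied_accuracy
LF_Area                 LF_Area           0.335            -0.931            0.661
LF_Perimeter       LF_Perimeter          -0.300            -2.449            0.354
LF_Eccentricity LF_Eccentricity           0.894            -0.415            0.857
LF_Intensity       LF_Intensity           0.947            -1.466            0.869
LF_Ratio               LF_Ratio           0.816            -0.832            0.836
Dependency (agreement) weights: -0.154 0.465
Class-prior weight: -1.107 (implied prevalence 0.099)

discarded mean-rule  min-rule
        7         9       184
```

The accuracy weights say how much each heuristic's vote moves the
posterior: eccentricity, intensity, and ratio are the reliable voters
(implied class-balanced accuracy 0.84–0.87), the positive-only perimeter
heuristic is nearly uninformative at this prevalence (its votes are
re-weighted as weak negative evidence), and the fitted class prior
(−1.11) corresponds to an implied prevalence of ~10%, near the planted
6%. Nine patients aggregate under the mean rule (confident BAV soft
labels), 184 under the min rule (confident TAV), and 7 are discarded —
the weak label set keeps 96.5% of patients.

```r
## train on the probabilistic labels and evaluate on held-out phantoms
ts  <- build_training_set(aligned[1:150], weak$patient_labels,
                          mode = "weak-balanced", size = 100, seed = 7)
ts  <- augment_training_set(ts, copies = 2, seed = 7)
man <- cohort_manifest(specs)
val_truth <- as.integer(man$truth[151:175] == "BAV")
mdl <- train_classifier(ts, aligned[151:175], val_truth, seed = 7)
pred <- predict(mdl, aligned[176:200])
th <- tune_threshold(predict(mdl, aligned[151:175])$prob, val_truth)
classification_metrics(as.integer(man$truth[176:200] == "BAV"),
                       pred$prob, th)
```

```
precision 25.0 | recall 100.0 | F1 40.0 | AUROC 91.7 | NDCG 50.0 (n = 25, threshold 0.453)
```

On the 25 held-out phantoms (a single true BAV at 6% prevalence) the
model ranks the positive near the top (AUROC 91.7) and recovers it at
the tuned threshold at the cost of three false alarms — the expected
picture for a weakly supervised model on a tiny, imbalanced test set.

The full study-scale protocol is one call:

```r
res <- scaleup_experiment(seed = 1)   # ~15 min on one CPU
res$summary                           # mean F1 per training-set size
```

A thin command-line wrapper over the staged pipeline lives at
`inst/cli/valveweak`
(`valveweak run --seed 1 --out run_dir`).

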