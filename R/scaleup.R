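## End-to-end weak-supervision drivers: cohort -> primitives -> label matrix
## -> label model -> patient labels -> classifier scale-up experiment.

#' Run the weak-labeling pipeline on preprocessed sequences
#'
#' Computes primitives, normalizes them with sex-stratified means from the
#' unlabeled pool, applies the labeling functions over the t-frame peak
#' windows, fits the generative label model, and aggregates frame marginals
#' into per-patient probabilistic labels.
#'
#' @param aligned Named list of `aligned_sequence`.
#' @param lfs Labeling functions (default [make_default_lfs()]).
#' @param t Labeling window size (default 6).
#' @param hi,lo Aggregation thresholds (defaults 0.9 / 0.5).
#' @param population_means Optional normalization means; computed from
#'   `aligned` when `NULL`.
#' @param seed Seed for the label-model fit.
#' @param ... Passed to [label_model()].
#' @return List with the normalized primitive table, label matrix, fitted
#'   model, frame marginals, patient labels, and the discard fraction.
#' @export
weak_label_cohort <- function(aligned, lfs = make_default_lfs(), t = 6,
                              hi = 0.9, lo = 0.5, population_means = NULL,
                              seed = 1L, ...) {
  prim <- compute_primitives(aligned)
  primn <- normalize_primitives(prim, population_means = population_means)
  peaks <- vapply(aligned, `[[`, integer(1), "peak_frame_original")
  names(peaks) <- vapply(aligned, `[[`, "", "patient_id")
  L <- apply_lfs(primn, lfs, peaks, t = t)
  deps <- infer_dependencies(lfs)
  model <- label_model(L, deps = deps, seed = seed, ...)
  ## symmetric-model marginals: the 0.9/0.5 aggregation thresholds assume
  ## the class-prior-free conditional (the prior cancels from rankings)
  probs <- marginals(model, L, use_prior = FALSE)
  patient_labels <- aggregate_patients(probs, attr(L, "frame_map"),
                                       hi = hi, lo = lo)
  list(primitives = primn, L = L, model = model, frame_probs = probs,
       patient_labels = patient_labels,
       discard_fraction = mean(patient_labels$provenance == "discarded"),
       population_means = attr(primn, "population_means"))
}

#' Weak-supervision scale-up experiment on a phantom cohort
#'
#' The study protocol at phantom scale: a cohort is split into an unlabeled
#' weak pool, a hand-labeled training split, and natural-prevalence
#' validation and test splits. The weak pool is labeled by the generative
#' pipeline; balanced weak training sets of growing size and a hand-labeled
#' oversampled baseline are trained with identical architectures across
#' several seeds, each with validation-based early stopping and threshold
#' tuning, and evaluated on the held-out test split.
#'
#' @param n_cohort Cohort size (default 1200).
#' @param prevalence BAV prevalence (default 0.06).
#' @param sizes Weak training-set sizes (default 50, 250, 1000).
#' @param n_seeds Model seeds per configuration (default 5).
#' @param split Patient counts for weak pool / hand split / validation /
#'   test (must sum to `n_cohort`).
#' @param config [classifier_config()] shared by all runs.
#' @param augment_copies Augmented copies added to every training set (the
#'   augmentation-enlarged protocol; 0 disables).
#' @param seed Master seed.
#' @param verbose Print per-run progress.
#' @return List with per-run results (`runs`), per-size mean F1 summaries
#'   (`summary`), the weak-labeling artifacts (`weak`), labeling-function
#'   gold metrics on the weak pool (`lf_metrics`), and the discard fraction.
#' @export
scaleup_experiment <- function(n_cohort = 1200, prevalence = 0.06,
                               sizes = c(50, 250, 1000), n_seeds = 5,
                               split = c(weak = 700, hand = 100,
                                         val = 100, test = 300),
                               config = classifier_config(max_steps = 3000),
                               augment_copies = 2, seed = 1L,
                               verbose = FALSE) {
  stopifnot(sum(split) == n_cohort)
  specs <- sample_cohort_specs(n_cohort, prevalence, seed = seed)
  manifest <- cohort_manifest(specs)
  aligned <- preprocess_cohort(specs, channels = "MAG")
  truth01 <- as.integer(manifest$truth == "BAV")

  idx <- with_seed(derive_seed(seed, 3, salt = 7), sample(n_cohort))
  weak_idx <- idx[seq_len(split["weak"])]
  hand_idx <- idx[split["weak"] + seq_len(split["hand"])]
  val_idx <- idx[split["weak"] + split["hand"] + seq_len(split["val"])]
  test_idx <- idx[split["weak"] + split["hand"] + split["val"] +
                    seq_len(split["test"])]

  weak <- weak_label_cohort(aligned[weak_idx],
                            seed = derive_seed(seed, 4, salt = 7))
  gold_frames <- ifelse(
    truth01[weak_idx][match(attr(weak$L, "frame_map")$patient_id,
                            manifest$patient_id[weak_idx])] == 1, 1L, -1L)
  lf_metrics <- lf_gold_metrics(weak$L, gold_frames)

  val_seqs <- aligned[val_idx]
  val_truth <- truth01[val_idx]
  test_seqs <- aligned[test_idx]
  test_truth <- truth01[test_idx]

  run_one <- function(train_set, run_seed) {
    if (augment_copies > 0) {
      train_set <- augment_training_set(train_set, copies = augment_copies,
                                        seed = run_seed)
    }
    mdl <- train_classifier(train_set, val_seqs, val_truth, config = config,
                            seed = run_seed)
    val_pred <- predict(mdl, val_seqs)
    th <- tune_threshold(val_pred$prob, val_truth)
    test_pred <- predict(mdl, test_seqs)
    mr <- classification_metrics(test_truth, test_pred$prob, th)
    list(f1 = mr$f1, precision = mr$precision, recall = mr$recall,
         auroc = mr$auroc, ndcg = mr$ndcg, threshold = th)
  }

  runs <- list()
  for (size in sizes) {
    for (s in seq_len(n_seeds)) {
      rs <- derive_seed(seed, s, salt = 100 + size)
      ts <- build_training_set(aligned[weak_idx], weak$patient_labels,
                               mode = "weak-balanced", size = size,
                               seed = rs)
      res <- run_one(ts, rs)
      runs[[length(runs) + 1]] <- data.frame(
        model = "weak", size = size, seed = s, f1 = res$f1,
        precision = res$precision, recall = res$recall, auroc = res$auroc,
        ndcg = res$ndcg, threshold = res$threshold)
      if (verbose) message(sprintf("weak size %d seed %d: F1 %.1f",
                                   size, s, res$f1))
    }
  }
  hand_labels <- data.frame(patient_id = manifest$patient_id[hand_idx],
                            truth = manifest$truth[hand_idx],
                            stringsAsFactors = FALSE)
  for (s in seq_len(n_seeds)) {
    rs <- derive_seed(seed, s, salt = 999)
    ts <- build_training_set(aligned[hand_idx], hand_labels,
                             mode = "hand-oversampled", seed = rs)
    res <- run_one(ts, rs)
    runs[[length(runs) + 1]] <- data.frame(
      model = "hand", size = length(hand_idx), seed = s, f1 = res$f1,
      precision = res$precision, recall = res$recall, auroc = res$auroc,
      ndcg = res$ndcg, threshold = res$threshold)
    if (verbose) message(sprintf("hand baseline seed %d: F1 %.1f", s,
                                 res$f1))
  }
  runs <- do.call(rbind, runs)
  agg <- stats::aggregate(f1 ~ model + size, data = runs, FUN = mean)
  list(runs = runs, summary = agg, weak = weak, lf_metrics = lf_metrics,
       discard_fraction = weak$discard_fraction,
       split = list(weak = weak_idx, hand = hand_idx, val = val_idx,
                    test = test_idx),
       manifest = manifest)
}
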