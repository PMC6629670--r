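test_that("noise-aware loss is the soft-label expectation of cross-entropy", {
  expect_equal(noise_aware_loss(0.8, 1), -log(0.8), tolerance = 1e-12)
  expect_equal(noise_aware_loss(0.5, 0.5), log(2), tolerance = 1e-12)
  ## linearity in the soft label
  p <- 0.73
  for (yhat in c(0.1, 0.4, 0.9)) {
    expect_equal(noise_aware_loss(p, yhat),
                 yhat * noise_aware_loss(p, 1) +
                   (1 - yhat) * noise_aware_loss(p, 0),
                 tolerance = 1e-12)
  }
  ## hard labels equal standard cross-entropy
  set.seed(4)
  probs <- runif(50, 0.01, 0.99)
  hard <- rbinom(50, 1, 0.5)
  ce <- mean(-hard * log(probs) - (1 - hard) * log(1 - probs))
  expect_equal(noise_aware_loss(probs, hard), ce, tolerance = 1e-12)
})

test_that("attention pooling returns a convex combination of frames", {
  feats <- matrix(rep(c(1, 2, 3), 4), 4, 3, byrow = TRUE)
  out <- attention_pool(feats, scores = rnorm(4))
  expect_equal(out$pooled, c(1, 2, 3), tolerance = 1e-12)
  expect_equal(sum(out$weights), 1, tolerance = 1e-6)

  set.seed(2)
  f2 <- matrix(rnorm(12), 4, 3)
  sharp <- attention_pool(f2, scores = c(0, 0, 50, 0))
  expect_equal(sharp$pooled, f2[3, ], tolerance = 1e-6)
  expect_true(all(attention_pool(f2, rnorm(4))$weights >= 0))
})

test_that("weak-balanced training sets draw size/2 from each bin", {
  fix <- mini_cohort()
  ids <- fix$manifest$patient_id
  labels <- data.frame(patient_id = ids,
                       prob = c(rep(0.9, 10), rep(0.5, 5), rep(0.1, 20),
                                rep(NA, 5)))
  ts <- build_training_set(fix$aligned, labels, "weak-balanced", size = 100,
                           seed = 8)
  expect_length(ts$sequences, 100)
  expect_equal(sum(ts$soft_labels > 0.5), 50)
  ## a probability of exactly 0.5 is in the negative bin
  expect_equal(unname(ts$manifest$bin_counts),
               c(10, 25))
  ## discarded (NA) patients never appear
  expect_false(any(names(ts$sequences) %in% ids[36:40]))

  ts2 <- build_training_set(fix$aligned, labels, "weak-balanced", size = 100,
                            seed = 8)
  expect_identical(names(ts$sequences), names(ts2$sequences))
  expect_identical(ts$soft_labels, ts2$soft_labels)

  bad <- labels; bad$prob <- 0.1
  expect_error(build_training_set(fix$aligned, bad, "weak-balanced"),
               "positive bin")
})

test_that("hand-oversampled training sets rebalance positives to parity", {
  fix <- mini_cohort()
  labels <- data.frame(patient_id = fix$manifest$patient_id,
                       truth = fix$manifest$truth)
  ts <- build_training_set(fix$aligned, labels, "hand-oversampled", seed = 1)
  n_neg <- sum(labels$truth == "TAV")
  expect_length(ts$sequences, 2 * n_neg)
  expect_equal(sum(ts$soft_labels == 1), n_neg)
  expect_true(all(ts$soft_labels %in% c(0, 1)))
})

test_that("augmentation applies one label-invariant transform per sequence", {
  fix <- mini_cohort()
  a <- fix$aligned[[1]]
  ident <- augment(a, augment_config(translate = 0, rotate = 0,
                                     scale = c(1, 1)), seed = 2)
  expect_identical(ident$frames, a$frames)

  shifted <- augment(a, augment_config(translate = 3, rotate = 0,
                                       scale = c(1, 1)), seed = 5)
  tf <- attr(shifted, "transform")
  expect_true(all(abs(tf$shift) <= 3))
  ## every frame shares the one transform: un-shifting any frame recovers it
  d <- dim(a$frames)
  for (t in c(1, d[1])) {
    orig <- a$frames[t, , , 1]
    got <- shifted$frames[t, , , 1]
    n <- nrow(orig)
    rs <- (1 + max(0, tf$shift[1])):(n + min(0, tf$shift[1]))
    cs <- (1 + max(0, tf$shift[2])):(n + min(0, tf$shift[2]))
    expect_equal(got[rs, cs], orig[rs - tf$shift[1], cs - tf$shift[2]])
  }
  expect_equal(dim(shifted$frames), dim(a$frames))

  rot <- augment(a, augment_config(translate = 2, rotate = 10,
                                   scale = c(0.9, 1.1)), seed = 9)
  expect_equal(dim(rot$frames), dim(a$frames))
  expect_true(all(rot$frames >= 0))
})

test_that("training is seeded, checkpointed, and 0-epoch safe", {
  fix <- mini_cohort()
  labels <- data.frame(patient_id = fix$manifest$patient_id[1:24],
                       truth = fix$manifest$truth[1:24])
  ts <- build_training_set(fix$aligned[1:24], labels, "hand-oversampled",
                           seed = 4)
  val <- fix$aligned[25:36]
  val_truth <- as.integer(fix$manifest$truth[25:36] == "BAV")
  cfg <- classifier_config(epochs = 3, min_epochs = 1, patience = 5)
  m1 <- train_classifier(ts, val, val_truth, config = cfg, seed = 12)
  m2 <- train_classifier(ts, val, val_truth, config = cfg, seed = 12)
  expect_identical(m1$params, m2$params)
  expect_equal(m1$log, m2$log)

  m0 <- train_classifier(ts, val, val_truth,
                         config = classifier_config(epochs = 0), seed = 12)
  expect_equal(nrow(m0$log), 0)
  expect_true(is.finite(m0$val_f1))

  expect_error(train_classifier(ts, val, rep(1L, 12),
                                config = cfg, seed = 1), "both classes")
})

test_that("prediction is batch-order invariant with bounded outputs", {
  fix <- mini_cohort()
  labels <- data.frame(patient_id = fix$manifest$patient_id[1:24],
                       truth = fix$manifest$truth[1:24])
  ts <- build_training_set(fix$aligned[1:24], labels, "hand-oversampled",
                           seed = 4)
  val_truth <- as.integer(fix$manifest$truth[25:36] == "BAV")
  mdl <- train_classifier(ts, fix$aligned[25:36], val_truth,
                          config = classifier_config(epochs = 5,
                                                     min_epochs = 1),
                          seed = 3)
  dup <- fix$aligned[c(37, 38, 37)]
  pred <- predict(mdl, dup)
  expect_equal(pred$prob[1], pred$prob[3], tolerance = 1e-12)
  emb <- attr(pred, "embeddings")
  expect_equal(emb[1, ], emb[3, ], tolerance = 1e-12)
  expect_equal(nrow(emb), 3)
  expect_true(all(pred$prob >= 0 & pred$prob <= 1))
  ## attention weights sum to one per patient
  expect_equal(unname(rowSums(attr(pred, "attention"))), rep(1, 3),
               tolerance = 1e-6)
})

test_that("threshold tuning maximizes F1 with lowest-threshold ties", {
  probs <- c(0.1, 0.15, 0.2, 0.8, 0.85, 0.9)
  labs <- c(0, 0, 0, 1, 1, 1)
  th <- tune_threshold(probs, labs)
  expect_gt(th, 0.2); expect_lt(th, 0.8)
  expect_equal(th, 0.5)                     # midpoint of the boundary pair

  ## equals exhaustive search at grid resolution 1e-4 (in achieved F1)
  set.seed(8)
  for (i in 1:10) {
    p <- runif(30)
    y <- rbinom(30, 1, 0.4)
    if (length(unique(y)) < 2) next
    th <- tune_threshold(p, y)
    f1_at <- function(t) classification_metrics(y, p, t)$f1
    grid_best <- max(vapply(seq(0, 1, by = 1e-4), f1_at, numeric(1)))
    expect_equal(f1_at(th), grid_best, tolerance = 1e-9)
  }

  expect_error(tune_threshold(runif(5), rep(1, 5)), "both classes")
  expect_error(tune_threshold(rep(0.4, 6), c(0, 1, 0, 1, 0, 1)),
               "degenerate")
})

test_that("a well-separated cohort is learned to high validation F1", {
  ## maximal class separation: circular calm TAV vs highly eccentric,
  ## irregular BAV; moderate cohort size keeps the run short
  base <- small_base_spec()
  specs <- sample_cohort_specs(160, prevalence = 0.5, base_spec = base,
                               seed = 404)
  specs$eccentricity_target <- ifelse(specs$truth == "BAV", 0.88, 0.10)
  specs$irregularity <- ifelse(specs$truth == "BAV", 0.45, 0.03)
  specs$flow_amplitude <- ifelse(specs$truth == "BAV", 0.55, 0.90)
  aligned <- preprocess_cohort(specs, channels = "MAG")
  man <- cohort_manifest(specs)
  labels <- data.frame(patient_id = man$patient_id[1:100],
                       truth = man$truth[1:100])
  ts <- build_training_set(aligned[1:100], labels, "hand-oversampled",
                           seed = 2)
  val_truth <- as.integer(man$truth[101:160] == "BAV")
  mdl <- train_classifier(ts, aligned[101:160], val_truth, seed = 5)
  expect_gte(mdl$val_f1, 90)
})
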