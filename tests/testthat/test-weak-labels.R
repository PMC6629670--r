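## Hand-built normalized primitive table: 2 patients x 2 frames with known
## values (feature columns already in normalized units).
toy_table <- function() {
  data.frame(
    patient_id = c("p1", "p1", "p2", "p2"),
    sex = "F",
    frame_index = c(9L, 10L, 9L, 10L),
    area = c(0.7, 0.9, 1.2, 1.0),
    perimeter = c(1.2, 1.0, 0.9, 1.0),
    eccentricity = c(1.5, 1.4, 0.8, 0.9),
    intensity = c(1.2, 1.3, 1.6, 1.5),
    ratio = c(0.9, 1.0, 1.2, 1.05),
    defined_area = TRUE, defined_perimeter = TRUE,
    defined_eccentricity = c(TRUE, TRUE, TRUE, FALSE),
    defined_intensity = TRUE, defined_ratio = TRUE)
}

test_that("default labeling functions have the expected names and wiring", {
  lfs <- make_default_lfs()
  expect_named(lfs, c("LF_Area", "LF_Perimeter", "LF_Eccentricity",
                      "LF_Intensity", "LF_Ratio"))
  expect_equal(sort(lfs$LF_Ratio$input_primitives), c("area", "perimeter"))
  expect_equal(lfs$LF_Perimeter$polarity, "positive")
  expect_equal(lfs$LF_Intensity$polarity, "negative")

  ## above the high eccentricity threshold -> BAV vote
  tab <- toy_table()
  tab$eccentricity <- lfs$LF_Eccentricity$high + 0.1
  votes <- valveweak:::eval_lf(lfs$LF_Eccentricity, tab)
  expect_equal(votes[1:3], rep(1L, 3))
  ## undefined primitive -> abstain, whatever the value
  expect_equal(votes[4], 0L)
})

test_that("label matrices cover the peak-centered window in order", {
  lfs <- make_default_lfs()
  tab <- do.call(rbind, lapply(0:29, function(f) {
    t1 <- toy_table()[c(1, 3), ]; t1$frame_index <- f; t1
  }))
  L <- apply_lfs(tab, lfs, peaks = c(p1 = 10L, p2 = 10L), t = 6)
  fm <- attr(L, "frame_map")
  expect_equal(nrow(L), 14)                      # 2 patients x 7 frames
  expect_equal(unique(fm$frame_index), 7:13)
  expect_equal(fm$patient_id, rep(c("p1", "p2"), each = 7))

  ## all-undefined primitives give all-abstain rows
  tab2 <- tab
  for (p in c("area", "perimeter", "eccentricity", "intensity", "ratio")) {
    tab2[[paste0("defined_", p)]] <- FALSE
  }
  L2 <- apply_lfs(tab2, lfs, peaks = c(p1 = 10L, p2 = 10L), t = 6)
  expect_true(all(L2 == 0L))

  ## clipped windows warn
  expect_warning(apply_lfs(tab[tab$frame_index <= 11, ], lfs,
                           peaks = c(p1 = 10L, p2 = 10L), t = 6),
                 "clipped")
})

test_that("hand-built fixture votes match manual threshold evaluation", {
  lfs <- make_default_lfs()
  tab <- toy_table()
  ## the fixture has only 2 of the 3 window frames -> clipping is expected
  L <- suppressWarnings(apply_lfs(tab, lfs, peaks = c(p1 = 10L, p2 = 10L),
                                  t = 2))
  ## manual evaluation against the packaged thresholds
  manual <- function(v, lf) {
    if (!is.na(lf$low) && v <= lf$low) return(lf$low_vote)
    if (!is.na(lf$high) && v >= lf$high) return(lf$high_vote)
    0L
  }
  fm <- attr(L, "frame_map")
  for (r in seq_len(nrow(L))) {
    row <- tab[tab$patient_id == fm$patient_id[r] &
                 tab$frame_index == fm$frame_index[r], ]
    for (j in seq_along(lfs)) {
      lf <- lfs[[j]]
      want <- if (all(unlist(row[paste0("defined_", lf$input_primitives)]))) {
        manual(row[[lf$feature]], lf)
      } else 0L
      expect_identical(unname(L[r, j]), as.integer(want))
    }
  }
})

test_that("coverage and conflict match their definitions", {
  L <- cbind(c(1L, -1L, 0L, 1L))
  expect_equal(lf_coverage(L, 1), 0.75)
  expect_equal(lf_coverage(matrix(0L, 5, 1), 1), 0)
  expect_equal(lf_coverage(matrix(1L, 5, 1), 1), 1)
  expect_equal(lf_conflict(L, 1), 0)             # single LF -> 0

  L2 <- rbind(c(1L, 1L), c(1L, -1L), c(0L, 1L))
  expect_equal(lf_conflict(L2, 1), 1 / 3)
  L3 <- cbind(c(1L, -1L, 0L), c(1L, -1L, 0L))
  expect_equal(unname(lf_conflict(L3)), c(0, 0))

  set.seed(5)
  for (i in 1:20) {
    Lr <- matrix(sample(c(-1L, 0L, 1L), 60, replace = TRUE), 20, 3)
    for (j in 1:3) {
      expect_identical(lf_conflict(Lr, j), brute_conflict(Lr, j))
      expect_equal(lf_coverage(Lr, j) + mean(Lr[, j] == 0), 1)
      expect_lte(lf_conflict(Lr, j), lf_coverage(Lr, j))
    }
  }
})

test_that("gold metrics count abstains as TAV and split accuracy by class", {
  gold <- c(1L, 1L, -1L, -1L, -1L, -1L)
  exact <- cbind(LF = gold)
  m <- lf_gold_metrics(exact, gold)
  expect_equal(m$precision, 100)
  expect_equal(m$recall, 100)
  expect_equal(m$f1, 100)

  silent <- cbind(LF = rep(0L, 6))
  m2 <- lf_gold_metrics(silent, gold)
  expect_equal(m2$recall, 0)
  expect_equal(m2$coverage, 0)

  ## hand-computed confusion matrix:
  ## votes: +1 on gold+, +1 on gold-, 0 on gold+, -1, 0, -1
  L <- cbind(LF = c(1L, 0L, 1L, -1L, 0L, -1L))
  m3 <- lf_gold_metrics(L, gold)
  ## effective labels: 1,-1,1,-1,-1,-1 -> tp=1 fp=1 fn=1
  expect_equal(m3$precision, 50)
  expect_equal(m3$recall, 50)
  expect_equal(m3$f1, 50)
  expect_equal(m3$pos_acc, 100)          # the only gold+ vote is correct
  expect_equal(m3$neg_acc, 100 * 2 / 3)  # votes on gold-: +1, -1, -1
  expect_equal(m3$coverage, 100 * 4 / 6)

  expect_error(lf_gold_metrics(L, integer(0)), "empty|align")
})

test_that("default LFs beat chance on a balanced cohort with deployment normalization", {
  ## deployment-style population means from an unlabeled 6%-prevalence
  ## cohort; accuracies evaluated at balanced prevalence (the accuracy the
  ## generative model parameterizes)
  base <- small_base_spec()
  dev_specs <- sample_cohort_specs(150, prevalence = 0.06, base_spec = base,
                                   seed = 71)
  dev_al <- preprocess_cohort(dev_specs, channels = "MAG")
  dev_norm <- normalize_primitives(compute_primitives(dev_al))
  means <- attr(dev_norm, "population_means")

  fix <- mini_cohort()
  primn <- normalize_primitives(compute_primitives(fix$aligned),
                                population_means = means)
  peaks <- setNames(fix$manifest$peak_frame, fix$manifest$patient_id)
  L <- apply_lfs(primn, make_default_lfs(), peaks, t = 6)
  fm <- attr(L, "frame_map")
  gold <- ifelse(fix$manifest$truth[match(fm$patient_id,
                                          fix$manifest$patient_id)] == "BAV",
                 1L, -1L)
  for (j in seq_len(ncol(L))) {
    nz <- L[, j] != 0
    expect_gt(mean(L[nz, j] == gold[nz]), 0.5)
  }
})

test_that("label matrices round-trip through CSV", {
  L <- matrix(sample(c(-1L, 0L, 1L), 30, replace = TRUE), 10, 3,
              dimnames = list(NULL, c("LF_A", "LF_B", "LF_C")))
  attr(L, "frame_map") <- data.frame(
    patient_id = rep(c("p1", "p2"), each = 5), frame_index = rep(0:4, 2),
    stringsAsFactors = FALSE)
  attr(L, "lf_names") <- colnames(L)
  class(L) <- c("label_matrix", class(L))
  path <- tempfile(fileext = ".csv")
  write_label_matrix(L, path)
  L2 <- read_label_matrix(path)
  expect_equal(unclass(L)[, ], unclass(L2)[, ])
  expect_equal(attr(L, "frame_map"), attr(L2, "frame_map"))
})
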