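test_that("classification metrics match hand-computed confusion matrices", {
  perfect <- classification_metrics(c(1, 1, 0, 0), c(0.9, 0.8, 0.2, 0.1))
  expect_equal(perfect$precision, 100)
  expect_equal(perfect$recall, 100)
  expect_equal(perfect$f1, 100)
  expect_equal(perfect$auroc, 100)

  m <- classification_metrics(c(1, 1, 0, 0), c(0.9, 0.4, 0.6, 0.1), 0.5)
  expect_equal(m$precision, 50)
  expect_equal(m$recall, 50)
  expect_equal(m$f1, 50)
  expect_equal(m$auroc, 75)

  one_class <- classification_metrics(c(1, 1), c(0.6, 0.7))
  expect_true(is.na(one_class$auroc))
  expect_equal(one_class$recall, 100)
})

test_that("AUROC is invariant under strictly monotone transforms", {
  set.seed(6)
  y <- rbinom(40, 1, 0.3)
  p <- runif(40)
  expect_equal(auroc(y, p), auroc(y, qlogis(p * 0.98 + 0.01)),
               tolerance = 1e-12)
  expect_equal(auroc(y, p), auroc(y, p^3), tolerance = 1e-12)
})

test_that("classification metrics agree with an independent enumeration", {
  set.seed(13)
  for (i in 1:50) {
    y <- rbinom(25, 1, 0.4)
    p <- runif(25)
    th <- runif(1)
    m <- classification_metrics(y, p, th)
    pred <- as.integer(p > th)
    tp <- sum(pred & y); fp <- sum(pred & !y); fn <- sum(!pred & y)
    prec <- if (tp + fp) 100 * tp / (tp + fp) else 0
    rec <- if (tp + fn) 100 * tp / (tp + fn) else 0
    expect_equal(m$precision, prec, tolerance = 1e-12)
    expect_equal(m$recall, rec, tolerance = 1e-12)
    if (prec + rec > 0) {
      expect_equal(m$f1, 2 * prec * rec / (prec + rec), tolerance = 1e-12)
    }
    ## rank-enumeration AUROC oracle
    if (any(y == 1) && any(y == 0)) {
      pairs <- expand.grid(i = which(y == 1), j = which(y == 0))
      want <- mean((p[pairs$i] > p[pairs$j]) + 0.5 * (p[pairs$i] == p[pairs$j]))
      expect_equal(m$auroc, 100 * want, tolerance = 1e-12)
    }
  }
})

test_that("NDCG follows the printed formula with stable ties", {
  expect_equal(as.numeric(ndcg(c(1, 1, 0, 0), c(0.9, 0.8, 0.2, 0.1))), 1)
  expect_equal(as.numeric(ndcg(c(0, 1, 0), c(0.9, 0.5, 0.2))),
               (1 / log2(3)) / 1, tolerance = 1e-12)
  expect_error(ndcg(c(0, 0), c(0.4, 0.2)), "positive")

  set.seed(21)
  for (i in 1:50) {
    y <- rbinom(30, 1, 0.3)
    if (!any(y == 1)) next
    p <- runif(30)
    expect_equal(as.numeric(ndcg(y, p)), brute_ndcg(y, p),
                 tolerance = 1e-12)
  }
  expect_true(attr(ndcg(c(1, 0), c(0.5, 0.5)), "ties"))
})

test_that("NDCG never decreases when a positive moves up the ranking", {
  set.seed(33)
  for (i in 1:30) {
    y <- rbinom(20, 1, 0.3)
    if (!any(y == 1) || !any(y == 0)) next
    p <- runif(20)
    ord <- order(-p)
    ranked_y <- y[ord]
    pos_ranks <- which(ranked_y == 1)
    pos <- pos_ranks[length(pos_ranks)]
    if (pos == 1) next
    swap <- ord
    tmp <- swap[pos]; swap[pos] <- swap[pos - 1]; swap[pos - 1] <- tmp
    p2 <- p
    p2[swap] <- sort(p, decreasing = TRUE)
    expect_gte(as.numeric(ndcg(y, p2)) + 1e-12, as.numeric(ndcg(y, p)))
  }
})

test_that("metric outputs stay within their declared bounds", {
  set.seed(44)
  for (i in 1:200) {
    y <- rbinom(15, 1, 0.5)
    p <- runif(15)
    m <- classification_metrics(y, p, runif(1))
    vals <- c(m$precision, m$recall, m$f1, m$auroc, m$ndcg)
    vals <- vals[!is.na(vals)]
    expect_true(all(vals >= 0 & vals <= 100))
  }
})

test_that("multi-seed summaries use a Student-t interval", {
  same <- summarize_runs(rep(61.4, 5))
  expect_equal(same$ci_lower, same$ci_upper)

  s <- summarize_runs(c(60, 62, 58, 61, 59))
  expect_equal(s$mean, 60)
  half <- qt(0.975, 4) * sd(c(60, 62, 58, 61, 59)) / sqrt(5)
  expect_equal(s$ci_lower, 60 - half, tolerance = 1e-12)
  expect_equal(s$ci_upper, 60 + half, tolerance = 1e-12)
  expect_equal(round(s$ci_upper - s$mean, 4), 1.9632)
  ## symmetry about the mean
  expect_equal(s$mean - s$ci_lower, s$ci_upper - s$mean, tolerance = 1e-12)

  lone <- summarize_runs(55)
  expect_false(lone$has_ci)
  expect_equal(lone$mean, 55)
})
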