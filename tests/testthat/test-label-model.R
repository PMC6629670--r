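fake_params <- function(theta, theta0 = 0) {
  list(lf_names = paste0("LF", seq_along(theta)),
       accuracy_weights = theta, class_prior_weight = theta0)
}

test_that("dependency inference links labeling functions sharing primitives", {
  lfs <- make_default_lfs()
  deps <- infer_dependencies(lfs)
  got <- apply(unclass(deps), 1, function(p) {
    paste(sort(attr(deps, "lf_names")[p]), collapse = "+")
  })
  expect_setequal(got, c("LF_Area+LF_Ratio", "LF_Perimeter+LF_Ratio"))
  expect_true(all(deps[, 1] != deps[, 2]))

  disjoint <- list(
    labeling_function("a", "area", low = 0.5, low_vote = 1L),
    labeling_function("b", "intensity", high = 1.5, high_vote = -1L))
  expect_equal(nrow(infer_dependencies(disjoint)), 0)

  ## order independence
  deps_rev <- infer_dependencies(rev(lfs))
  expect_equal(nrow(deps_rev), 2)
})

test_that("marginals have the two-state closed form", {
  p1 <- marginals(fake_params(1), cbind(1L))
  expect_equal(p1, exp(1) / (exp(1) + exp(-1)), tolerance = 1e-12)
  expect_equal(marginals(fake_params(c(1, 2)), rbind(c(0L, 0L))), 0.5)
})

test_that("marginals equal full-joint enumeration on random rows", {
  set.seed(12)
  n <- 5
  deps <- rbind(c(1L, 3L), c(2L, 5L))
  for (rep in 1:50) {
    theta <- rnorm(n)
    theta_lab <- rnorm(n)
    theta_dep <- rnorm(2)
    theta0 <- rnorm(1, 0, 0.5)
    L <- matrix(sample(c(-1L, 0L, 1L), 20 * n, replace = TRUE), 20, n)
    got <- marginals(fake_params(theta, theta0), L)
    for (i in 1:20) {
      want <- enum_marginal(L[i, ], theta, theta_lab, theta0, deps,
                            theta_dep)
      expect_lt(abs(got[i] - want), 1e-10)
    }
  }
})

test_that("sign symmetry: negating votes and weights mirrors marginals", {
  set.seed(3)
  theta <- runif(4, 0.2, 1.5)
  L <- matrix(sample(c(-1L, 0L, 1L), 80, replace = TRUE), 20, 4)
  p <- marginals(fake_params(theta), L)
  p_neg <- marginals(fake_params(-theta), -L)
  expect_equal(abs(p - 0.5), abs(p_neg - 0.5), tolerance = 1e-12)
})

test_that("fitting is deterministic and recovers accuracy ordering", {
  sim <- sample_label_matrix(
    10000, list(lf_sim_params(0.9, 1), lf_sim_params(0.75, 1),
                lf_sim_params(0.6, 1)), class_balance = 0.5, seed = 61)
  m1 <- label_model(sim$L, seed = 17)
  m2 <- label_model(sim$L, seed = 17)
  expect_identical(coef(m1), coef(m2))
  th <- unname(m1$accuracy_weights)
  expect_true(th[1] > th[2] && th[2] > th[3])
})

test_that("a coin-flip LF inside an ensemble gets near-zero weight", {
  sim <- sample_label_matrix(
    20000, list(lf_sim_params(0.85, 0.9), lf_sim_params(0.8, 0.9),
                lf_sim_params(0.5, 0.8)), class_balance = 0.5, seed = 23)
  m <- label_model(sim$L, seed = 29)
  expect_lt(abs(unname(m$accuracy_weights[3])), 0.1)
})

test_that("zero-coverage LFs are dropped with a warning", {
  sim <- sample_label_matrix(500, list(lf_sim_params(0.8, 1),
                                       lf_sim_params(0.8, 0)), seed = 2)
  expect_warning(m <- label_model(sim$L, epochs = 20, seed = 1),
                 "zero-coverage")
  expect_true(is.na(m$accuracy_weights[2]))
  p <- marginals(m, sim$L)
  expect_true(all(is.finite(p)))
})

test_that("majority vote follows the sign of summed votes", {
  expect_equal(majority_vote(rbind(c(1L, 1L, -1L))), 1L)
  expect_equal(majority_vote(rbind(c(1L, -1L, 0L))), 0L)
  expect_equal(majority_vote(rbind(c(0L, 0L, 0L))), 0L)
})

test_that("patient aggregation applies mean, min, then discard", {
  a <- aggregate_patient(c(0.95, 0.92, 0.96, 0.93, 0.94, 0.98))
  expect_equal(a$provenance, "mean-rule")
  expect_equal(a$value, mean(c(0.95, 0.92, 0.96, 0.93, 0.94, 0.98)),
               tolerance = 1e-12)
  expect_equal(round(a$value, 4), 0.9467)

  b <- aggregate_patient(c(0.8, 0.7, 0.3, 0.6, 0.7, 0.65))
  expect_equal(b$provenance, "min-rule")
  expect_equal(b$value, 0.3)

  d <- aggregate_patient(c(0.7, 0.8, 0.6, 0.75, 0.7, 0.65))
  expect_equal(d$provenance, "discarded")
  expect_true(is.na(d$value))

  expect_error(aggregate_patient(numeric(0)), "empty")

  ## totality: every random list lands in exactly one branch
  set.seed(9)
  for (i in 1:200) {
    pl <- aggregate_patient(runif(6))
    expect_true(pl$provenance %in% c("mean-rule", "min-rule", "discarded"))
  }
})

test_that("aggregate_patients maps frames to one row per patient", {
  fm <- data.frame(patient_id = rep(c("a", "b"), each = 3))
  probs <- c(0.95, 0.96, 0.97, 0.2, 0.6, 0.7)
  out <- aggregate_patients(probs, fm)
  expect_equal(out$provenance, c("mean-rule", "min-rule"))
  expect_equal(out$prob, c(0.96, 0.2))
})

test_that("label model serializes to JSON with its weights", {
  sim <- sample_label_matrix(400, list(lf_sim_params(0.8, 1),
                                       lf_sim_params(0.7, 1)), seed = 5)
  m <- label_model(sim$L, epochs = 30, seed = 3)
  path <- tempfile(fileext = ".json")
  write_label_model(m, path)
  back <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_equal(back$accuracy_weights, unname(m$accuracy_weights),
               tolerance = 1e-12)
  expect_equal(back$seed, 3)
})
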