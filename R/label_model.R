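## Generative factor-graph label model.
##
## The joint over votes Lambda and latent frame labels y in {-1, +1} is
##
##   p_theta(Lambda, Y) propto exp( sum_i [ theta0 * y_i
##       + sum_j  thetaAcc_j  * y_i * Lambda_ij
##       + sum_j  thetaLab_j  * 1(Lambda_ij != 0)
##       + sum_(j,k) in deps theta_jk * 1(Lambda_ij == Lambda_ik) ] )
##
## Accuracy factors couple votes to the latent label; labeling-propensity
## factors absorb each LF's abstain rate (without them the accuracy weight
## is forced to track propensity rather than accuracy); agreement factors
## model the redundancy of LFs sharing input primitives; the optional class
## prior absorbs class imbalance. Only the accuracy weights and the class
## prior involve y, so the posterior marginal has the closed form
##   P(y_i = 1 | Lambda_i) = logistic(2 * (theta0 + sum_j thetaAcc_j
##                                                     * Lambda_ij)).
## Weights are estimated by persistent contrastive divergence: SGD whose
## gradient expectations are estimated by Gibbs sampling (positive phase
## clamps Lambda and samples y; negative phase samples both from a
## persistent chain).

#' Infer dependencies among labeling functions from shared primitives
#'
#' Two LFs are declared dependent when their `input_primitives` sets
#' intersect (e.g., a ratio-based LF depends on the separate area and
#' perimeter LFs). Pairs are unordered, without self-pairs.
#'
#' @param lfs List of [labeling_function()]s.
#' @return Object of class `dependency_set`: integer matrix with columns
#'   `j`, `k` (j < k) and attribute `lf_names`; the dependency type of every
#'   pair is `"similarity"`.
#' @export
infer_dependencies <- function(lfs) {
  n <- length(lfs)
  pairs <- NULL
  if (n >= 2) {
    for (j in seq_len(n - 1)) {
      for (k in (j + 1):n) {
        if (length(intersect(lfs[[j]]$input_primitives,
                             lfs[[k]]$input_primitives))) {
          pairs <- rbind(pairs, c(j, k))
        }
      }
    }
  }
  if (is.null(pairs)) pairs <- matrix(integer(0), 0, 2)
  colnames(pairs) <- c("j", "k")
  structure(pairs, lf_names = vapply(lfs, `[[`, "", "name"),
            type = "similarity", class = c("dependency_set", "matrix"))
}

## Sample y | Lambda (vectorized over rows).
.sample_y <- function(L, theta_acc, theta0) {
  p <- logistic(2 * (as.vector(L %*% theta_acc) + theta0))
  ifelse(stats::runif(nrow(L)) < p, 1L, -1L)
}

## One Gibbs sweep over the columns of the chain state Lt given yt.
.sweep_columns <- function(Lt, yt, theta_acc, theta_lab, deps, theta_dep) {
  m <- nrow(Lt)
  for (j in seq_len(ncol(Lt))) {
    lp_m <- -theta_acc[j] * yt + theta_lab[j]
    lp_z <- numeric(m)
    lp_p <- theta_acc[j] * yt + theta_lab[j]
    if (nrow(deps)) {
      for (d in which(deps[, 1] == j | deps[, 2] == j)) {
        k <- if (deps[d, 1] == j) deps[d, 2] else deps[d, 1]
        lp_m <- lp_m + theta_dep[d] * (Lt[, k] == -1L)
        lp_z <- lp_z + theta_dep[d] * (Lt[, k] == 0L)
        lp_p <- lp_p + theta_dep[d] * (Lt[, k] == 1L)
      }
    }
    mx <- pmax(lp_m, lp_z, lp_p)
    em <- exp(lp_m - mx); ez <- exp(lp_z - mx); ep <- exp(lp_p - mx)
    u <- stats::runif(m) * (em + ez + ep)
    Lt[, j] <- ifelse(u < em, -1L, ifelse(u < em + ez, 0L, 1L))
  }
  Lt
}

#' Fit the generative label model
#'
#' Estimates accuracy, propensity, dependency, and (optionally) class-prior
#' weights by persistent contrastive divergence, maximizing the marginal
#' likelihood of the observed label matrix with the latent frame labels
#' marginalized by Gibbs sampling. Deterministic under `seed`.
#'
#' @param L Label matrix in {-1, 0, 1} (plain matrix or [apply_lfs()]
#'   output). LFs with zero coverage are dropped with a warning (their
#'   accuracy weights are unidentifiable); their weights are reported as
#'   `NA` and treated as 0 at inference.
#' @param deps A [infer_dependencies()] set, or `NULL` for none.
#' @param class_prior `"fit"` (default) learns the class-prior weight
#'   alongside the other factors, a number fixes it (0 recovers the
#'   symmetric model), and a prevalence estimate can be supplied as
#'   `log(p/(1-p))/2` via [prevalence_prior()].
#' @param epochs Number of full-batch gradient updates (default 250).
#' @param step_size SGD step size (default 0.05).
#' @param gibbs_sweeps Gibbs sweeps of the persistent negative chain per
#'   update (default 2).
#' @param init_accuracy Initial accuracy weight (default 0.7, encoding the
#'   better-than-chance assumption on labeling functions; a symmetric start
#'   at 0 makes the sign of the solution a coin flip).
#' @param tail Fraction of the weight trajectory averaged for the final
#'   estimate (default 0.4).
#' @param seed Integer seed.
#' @param verbose Print progress.
#' @return Object of class `label_model` with accuracy/propensity/dependency
#'   weights, the class-prior weight, hyperparameters, and the seed.
#' @export
label_model <- function(L, deps = NULL, class_prior = "fit",
                        epochs = 250, step_size = 0.05, gibbs_sweeps = 2,
                        init_accuracy = 0.7, tail = 0.4, seed = 1L,
                        verbose = FALSE) {
  lf_names <- colnames(L) %||% paste0("LF", seq_len(ncol(L)))
  L <- matrix(as.integer(L), nrow(L), ncol(L))
  if (!all(L %in% c(-1L, 0L, 1L))) stop("label matrix entries must be -1/0/1",
                                        call. = FALSE)
  if (nrow(L) == 0) stop("empty label matrix", call. = FALSE)
  cov <- colMeans(L != 0)
  keep <- which(cov > 0)
  if (length(keep) < ncol(L)) {
    warning(sprintf("dropping %d zero-coverage labeling function(s): %s",
                    ncol(L) - length(keep),
                    paste(lf_names[cov == 0], collapse = ", ")))
  }
  if (!length(keep)) stop("all labeling functions have zero coverage",
                          call. = FALSE)
  Lk <- L[, keep, drop = FALSE]
  n <- ncol(Lk); m <- nrow(Lk)

  dep_pairs <- matrix(integer(0), 0, 2)
  if (!is.null(deps) && nrow(deps)) {
    ## re-index dependency pairs onto kept columns
    remap <- match(seq_len(ncol(L)), keep)
    dp <- cbind(remap[deps[, 1]], remap[deps[, 2]])
    dep_pairs <- dp[stats::complete.cases(dp), , drop = FALSE]
    storage.mode(dep_pairs) <- "integer"
  }
  nd <- nrow(dep_pairs)

  fit_prior <- identical(class_prior, "fit")
  theta0 <- if (fit_prior) 0 else as.numeric(class_prior)
  theta_acc <- rep(init_accuracy, n)
  theta_lab <- rep(0, n)
  theta_dep <- rep(0, nd)
  hist_acc <- matrix(0, epochs, n)
  hist0 <- numeric(epochs)
  hist_dep <- matrix(0, epochs, max(nd, 1))

  with_seed(seed, {
    ## data-side moments that do not depend on y
    gpos_lab <- colMeans(Lk != 0)
    gpos_dep <- if (nd) vapply(seq_len(nd), function(d) {
      mean(Lk[, dep_pairs[d, 1]] == Lk[, dep_pairs[d, 2]])
    }, numeric(1)) else numeric(0)

    Lt <- Lk
    yt <- .sample_y(Lk, theta_acc, theta0)
    for (ep in seq_len(epochs)) {
      ## positive phase: clamp Lambda, sample y
      ypos <- .sample_y(Lk, theta_acc, theta0)
      gpos_acc <- as.vector(crossprod(Lk, ypos)) / m
      gpos_0 <- mean(ypos)
      ## negative phase: persistent Gibbs chain over (Lambda, y)
      for (s in seq_len(gibbs_sweeps)) {
        Lt <- .sweep_columns(Lt, yt, theta_acc, theta_lab, dep_pairs,
                             theta_dep)
        yt <- .sample_y(Lt, theta_acc, theta0)
      }
      gneg_acc <- as.vector(crossprod(Lt, yt)) / m
      gneg_lab <- colMeans(Lt != 0)
      gneg_0 <- mean(yt)
      grad_acc <- gpos_acc - gneg_acc
      if (any(!is.finite(grad_acc))) {
        stop("non-finite gradient during label-model fitting; epoch ", ep,
             call. = FALSE)
      }
      theta_acc <- theta_acc + step_size * grad_acc
      theta_lab <- theta_lab + step_size * (gpos_lab - gneg_lab)
      if (fit_prior) theta0 <- theta0 + step_size * (gpos_0 - gneg_0)
      if (nd) {
        gneg_dep <- vapply(seq_len(nd), function(d) {
          mean(Lt[, dep_pairs[d, 1]] == Lt[, dep_pairs[d, 2]])
        }, numeric(1))
        theta_dep <- theta_dep + step_size * (gpos_dep - gneg_dep)
        hist_dep[ep, seq_len(nd)] <- theta_dep
      }
      hist_acc[ep, ] <- theta_acc
      hist0[ep] <- theta0
      if (verbose && ep %% 50 == 0) {
        message(sprintf("epoch %d: theta_acc = %s", ep,
                        paste(sprintf("%.3f", theta_acc), collapse = " ")))
      }
    }
  })

  avg_from <- ceiling(epochs * (1 - tail))
  theta_acc <- colMeans(hist_acc[avg_from:epochs, , drop = FALSE])
  theta0 <- mean(hist0[avg_from:epochs])
  if (nd) {
    theta_dep <- colMeans(hist_dep[avg_from:epochs, seq_len(nd),
                                   drop = FALSE])
  }

  acc_full <- rep(NA_real_, ncol(L))
  acc_full[keep] <- theta_acc
  lab_full <- rep(NA_real_, ncol(L))
  lab_full[keep] <- theta_lab
  names(acc_full) <- names(lab_full) <- lf_names

  structure(list(
    lf_names = lf_names,
    accuracy_weights = acc_full,
    propensity_weights = lab_full,
    dependency = if (!is.null(deps)) deps else NULL,
    dependency_weights = if (nd) theta_dep else numeric(0),
    class_prior_weight = theta0,
    kept = keep,
    hyper = list(epochs = epochs, step_size = step_size,
                 gibbs_sweeps = gibbs_sweeps, init_accuracy = init_accuracy,
                 tail = tail, class_prior = class_prior),
    seed = as.integer(seed)
  ), class = "label_model")
}

#' Class-prior weight from a prevalence estimate
#'
#' @param prevalence Estimated positive-class prevalence.
#' @return The factor weight `log(p / (1 - p)) / 2`.
#' @export
prevalence_prior <- function(prevalence) {
  stopifnot_prob(prevalence, "prevalence")
  0.5 * log(prevalence / (1 - prevalence))
}

#' Posterior frame marginals under a label model
#'
#' Exact per-row conditional by two-state enumeration: with
#' `s_i = theta0 + sum_j theta_j Lambda_ij`,
#' `P(y_i = 1 | Lambda_i) = exp(s_i) / (exp(s_i) + exp(-s_i))`; factors not
#' involving y (propensity, dependency) cancel from the conditional.
#'
#' @param params A fitted [label_model()] (or any list with
#'   `accuracy_weights` and `class_prior_weight`).
#' @param L Label matrix with columns matching `params$lf_names`.
#' @param use_prior Include the class-prior weight in `s_i`. The prior
#'   de-biases weight estimation under class imbalance but shifts every
#'   marginal identically (rankings are unchanged); the patient-aggregation
#'   thresholds are calibrated for the symmetric-model marginal, so the
#'   weak-labeling pipeline aggregates with `use_prior = FALSE`.
#' @return Numeric vector of `P(y = 1 | Lambda)` per row.
#' @export
marginals <- function(params, L, use_prior = TRUE) {
  th <- params$accuracy_weights
  th[is.na(th)] <- 0
  if (ncol(L) != length(th)) stop("label matrix has wrong number of columns",
                                  call. = FALSE)
  s <- as.vector(matrix(as.numeric(L), nrow(L)) %*% th)
  if (use_prior) s <- s + params$class_prior_weight
  logistic(2 * s)
}

#' @export
predict.label_model <- function(object, L, type = c("prob", "label"),
                                use_prior = TRUE, ...) {
  p <- marginals(object, L, use_prior = use_prior)
  if (match.arg(type) == "prob") p else ifelse(p > 0.5, 1L, -1L)
}

#' @export
coef.label_model <- function(object, ...) {
  list(accuracy = object$accuracy_weights,
       propensity = object$propensity_weights,
       dependency = object$dependency_weights,
       class_prior = object$class_prior_weight)
}

#' @export
print.label_model <- function(x, ...) {
  cat("<label_model> fitted by persistent contrastive divergence\n")
  cat(sprintf("  %d labeling functions; class-prior weight %.3f\n",
              length(x$lf_names), x$class_prior_weight))
  print(round(x$accuracy_weights, 3))
  invisible(x)
}

#' @export
summary.label_model <- function(object, ...) {
  out <- data.frame(
    lf = object$lf_names,
    accuracy_weight = unname(object$accuracy_weights),
    propensity_weight = unname(object$propensity_weights),
    implied_accuracy = logistic(2 * unname(object$accuracy_weights)),
    stringsAsFactors = FALSE
  )
  cat("Label model weights (implied accuracy = logistic(2 * weight)):\n")
  print(out, digits = 3)
  if (length(object$dependency_weights)) {
    cat("Dependency (agreement) weights:",
        paste(sprintf("%.3f", object$dependency_weights), collapse = " "),
        "\n")
  }
  cat(sprintf("Class-prior weight: %.3f (implied prevalence %.3f)\n",
              object$class_prior_weight,
              logistic(2 * object$class_prior_weight)))
  invisible(out)
}

#' Majority-vote baseline
#'
#' Hard per-frame label from the sign of the summed votes; zero sums
#' (including all-abstain rows) are undecided (0).
#'
#' @param L Label matrix.
#' @return Integer vector in {-1, 0, 1}.
#' @export
majority_vote <- function(L) {
  as.integer(sign(rowSums(L)))
}

#' Aggregate frame probabilities to one patient label
#'
#' Applies the mean rule first (mean > `hi` keeps the mean), then the min
#' rule (min < `lo` keeps the minimum), otherwise the patient is discarded.
#'
#' @param frame_probs Probabilities of the patient's window frames.
#' @param hi Mean-rule threshold (default 0.9).
#' @param lo Min-rule threshold (default 0.5).
#' @return Object of class `patient_label`: list with `value` (probability,
#'   or `NA` when discarded) and `provenance` (`"mean-rule"`, `"min-rule"`,
#'   or `"discarded"`).
#' @export
aggregate_patient <- function(frame_probs, hi = 0.9, lo = 0.5) {
  if (length(frame_probs) == 0) stop("empty probability list", call. = FALSE)
  stopifnot_prob(frame_probs, "frame_probs")
  if (mean(frame_probs) > hi) {
    out <- list(value = mean(frame_probs), provenance = "mean-rule")
  } else if (min(frame_probs) < lo) {
    out <- list(value = min(frame_probs), provenance = "min-rule")
  } else {
    out <- list(value = NA_real_, provenance = "discarded")
  }
  structure(out, class = "patient_label")
}

#' Aggregate all patients of a frame-probability table
#'
#' @param frame_probs Probabilities per row of `frame_map`.
#' @param frame_map data.frame with `patient_id` per row (e.g., the
#'   `frame_map` attribute of [apply_lfs()]).
#' @inheritParams aggregate_patient
#' @return data.frame: patient_id, prob (NA when discarded), provenance.
#' @export
aggregate_patients <- function(frame_probs, frame_map, hi = 0.9, lo = 0.5) {
  ids <- unique(frame_map$patient_id)
  rows <- lapply(ids, function(id) {
    pl <- aggregate_patient(frame_probs[frame_map$patient_id == id], hi, lo)
    data.frame(patient_id = id, prob = pl$value, provenance = pl$provenance,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Serialize a fitted label model to JSON
#'
#' @param model A [label_model()].
#' @param path Output path.
#' @export
write_label_model <- function(model, path) {
  obj <- list(lf_names = model$lf_names,
              accuracy_weights = unname(model$accuracy_weights),
              propensity_weights = unname(model$propensity_weights),
              dependency_pairs = if (!is.null(model$dependency))
                unclass(model$dependency)[, , drop = FALSE] else NULL,
              dependency_weights = model$dependency_weights,
              class_prior_weight = model$class_prior_weight,
              hyper = model$hyper, seed = model$seed)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}
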