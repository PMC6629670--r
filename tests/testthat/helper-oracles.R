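## Independent brute-force oracles used across tests.

## Full-joint enumeration of P(y = 1 | Lambda_i) including propensity and
## dependency factors (which must cancel), for one row.
enum_marginal <- function(row, theta_acc, theta_lab, theta0, deps,
                          theta_dep) {
  joint <- function(y) {
    s <- sum(theta_acc * y * row) + theta0 * y + sum(theta_lab * (row != 0))
    if (!is.null(deps) && nrow(deps)) {
      for (d in seq_len(nrow(deps))) {
        s <- s + theta_dep[d] * (row[deps[d, 1]] == row[deps[d, 2]])
      }
    }
    exp(s)
  }
  joint(1) / (joint(1) + joint(-1))
}

## Brute-force sliding-window localization.
brute_localize <- function(vals, size) {
  best <- -Inf; best_rc <- c(1, 1)
  for (r in 1:(nrow(vals) - size + 1)) {
    for (c in 1:(ncol(vals) - size + 1)) {
      s <- sum(vals[r:(r + size - 1), c:(c + size - 1)])
      if (s > best + 1e-12) { best <- s; best_rc <- c(r, c) }
    }
  }
  list(top = best_rc[1] - 1L, left = best_rc[2] - 1L)
}

## Brute-force per-row conflict scan.
brute_conflict <- function(L, j) {
  cnt <- 0
  for (i in seq_len(nrow(L))) {
    if (L[i, j] == 0) next
    for (k in seq_len(ncol(L))) {
      if (k != j && L[i, k] != 0 && L[i, k] != L[i, j]) { cnt <- cnt + 1; break }
    }
  }
  cnt / nrow(L)
}

## Brute-force NDCG by direct formula evaluation.
brute_ndcg <- function(truth, probs) {
  ord <- order(-probs)
  rel <- as.integer(truth == 1)[ord]
  dcg <- sum(rel / log2(seq_along(rel) + 1))
  ideal <- sum(sort(as.integer(truth == 1), decreasing = TRUE) /
                 log2(seq_along(truth) + 1))
  dcg / ideal
}

## Rasterize an ellipse mask (axes a, b in pixels, rotation theta).
raster_ellipse <- function(n, a, b, theta = 0, center = NULL) {
  if (is.null(center)) center <- c((n + 1) / 2, (n + 1) / 2)
  r <- matrix(seq_len(n), n, n) - center[1]
  c <- matrix(seq_len(n), n, n, byrow = TRUE) - center[2]
  u <- r * cos(theta) + c * sin(theta)
  v <- -r * sin(theta) + c * cos(theta)
  matrix(as.integer(u^2 / a^2 + v^2 / b^2 <= 1), n, n)
}
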