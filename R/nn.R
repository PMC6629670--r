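## Minimal neural-network engine for the sequence classifier.
##
## Layout conventions: a batch of N grayscale frames is a matrix
## [H*W, N] with R's column-major pixel order; multi-channel feature maps
## stack channels in row blocks (row = (c-1)*npix + p). Convolutions are
## evaluated as im2col matrix products; gradients are hand-derived.
## Everything is plain double-precision BLAS, deterministic under seed in
## single-thread mode.

relu <- function(x) (x > 0) * x

## ---- convolution -----------------------------------------------------

conv_geom <- function(h_in, w_in, c_in, k_filters, kern, stride) {
  h_out <- floor((h_in - kern) / stride) + 1
  w_out <- floor((w_in - kern) / stride) + 1
  npos <- h_out * w_out
  ## im2col index: rows = kern^2 * c_in receptive-field entries,
  ## cols = output positions (column-major over the output grid)
  idx <- matrix(0L, kern * kern * c_in, npos)
  pos <- 0L
  for (oc in seq_len(w_out)) {
    for (orow in seq_len(h_out)) {
      pos <- pos + 1L
      r0 <- (orow - 1L) * stride
      c0 <- (oc - 1L) * stride
      ent <- 0L
      for (ch in seq_len(c_in)) {
        for (kc in seq_len(kern)) {
          for (kr in seq_len(kern)) {
            ent <- ent + 1L
            idx[ent, pos] <- (ch - 1L) * h_in * w_in +
              (c0 + kc - 1L) * h_in + (r0 + kr)
          }
        }
      }
    }
  }
  list(h_in = h_in, w_in = w_in, c_in = c_in, k = k_filters, kern = kern,
       stride = stride, h_out = h_out, w_out = w_out, npos = npos, idx = idx)
}

conv_forward <- function(X, W, b, geom) {
  N <- ncol(X)
  PM <- im2col_cpp(X, geom$idx)
  Z <- PM %*% W
  br <- bias_relu_split_cpp(Z, b, geom$npos, N)
  list(out = br$out, PM = PM, A = br$A, N = N)
}

conv_backward <- function(dOut, cache, W, geom, need_dx = FALSE) {
  N <- cache$N
  dZ <- join_mask_cpp(dOut, cache$A, geom$npos, N)
  dW <- crossprod(cache$PM, dZ)
  db <- colSums(dZ)
  dX <- NULL
  if (need_dx) {
    dPM <- dZ %*% t(W)
    dX <- col2im_cpp(dPM, geom$idx, geom$h_in * geom$w_in * geom$c_in)
  }
  list(dW = dW, db = db, dX = dX)
}

## Global average pooling over spatial positions, per channel.
gap_forward <- function(out, geom) {
  arr <- array(out, c(geom$npos, geom$k, ncol(out)))
  t(colMeans(arr))               # [N, K]
}

gap_backward <- function(dF, geom) {
  gap_backward_cpp(dF, geom$npos)
}

## ---- parameter containers --------------------------------------------

nn_init_params <- function(config, seed) {
  with_seed(seed, {
    conv <- list()
    geoms <- list()
    h <- config$input_size; w <- config$input_size; cin <- 1L
    for (l in seq_along(config$conv_filters)) {
      geom <- conv_geom(h, w, cin, config$conv_filters[l],
                        config$kernel[l], config$stride[l])
      fan_in <- config$kernel[l]^2 * cin
      conv[[l]] <- list(
        W = matrix(stats::rnorm(fan_in * geom$k, 0, sqrt(2 / fan_in)),
                   fan_in, geom$k),
        b = numeric(geom$k))
      geoms[[l]] <- geom
      h <- geom$h_out; w <- geom$w_out; cin <- geom$k
    }
    D <- cin
    H <- config$hidden
    A <- config$attn_dim
    mk_rnn <- function() list(
      Wx = matrix(stats::rnorm(D * H, 0, sqrt(1 / D)), D, H),
      Wh = matrix(stats::rnorm(H * H, 0, 0.5 * sqrt(1 / H)), H, H),
      b = numeric(H))
    list(params = list(conv = conv,
                       rnn_f = mk_rnn(), rnn_b = mk_rnn(),
                       attn = list(Wa = matrix(stats::rnorm(2 * H * A, 0,
                                                 sqrt(1 / (2 * H))), 2 * H, A),
                                   ba = numeric(A),
                                   v = stats::rnorm(A, 0, sqrt(1 / A))),
                       head = list(w = matrix(stats::rnorm(2 * H + D, 0,
                                                sqrt(1 / (2 * H + D))),
                                              2 * H + D, 1),
                                   b = 0)),
         geoms = geoms, feature_dim = D)
  })
}

## Recursive walkers over nested parameter lists (leaves = numeric arrays).
nn_map <- function(p, f) {
  if (is.list(p)) {
    out <- lapply(p, nn_map, f = f)
    return(out)
  }
  if (is.numeric(p)) f(p) else p
}

nn_map2 <- function(a, b, f) {
  if (is.list(a)) {
    out <- a
    for (nm in seq_along(a)) out[[nm]] <- nn_map2(a[[nm]], b[[nm]], f)
    return(out)
  }
  if (is.numeric(a)) f(a, b) else a
}

## Adam step; state holds first/second moments mirroring the params.
adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1
  state$m <- nn_map2(state$m, grads, function(m, g) beta1 * m + (1 - beta1) * g)
  state$v <- nn_map2(state$v, grads, function(v, g) beta2 * v + (1 - beta2) * g^2)
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  upd <- nn_map2(state$m, state$v,
                 function(m, v) lr * (m / bc1) / (sqrt(v / bc2) + eps))
  params <- nn_map2(params, upd, function(p, u) p - u)
  list(params = params, state = state)
}

adam_init <- function(params) {
  zeros <- nn_map(params, function(x) x * 0)
  list(m = zeros, v = zeros, t = 0)
}

## Feature standardization between the conv encoder and the sequence
## encoder: fixed affine (mu, sd) computed from the training set at
## initialization, so the recurrent stack sees O(1) inputs regardless of
## filter scale.
nn_feat_stats <- function(params, geoms, X) {
  cur <- X
  for (l in seq_along(params$conv)) {
    cur <- conv_forward(cur, params$conv[[l]]$W, params$conv[[l]]$b,
                        geoms[[l]])$out
  }
  FM <- gap_forward(cur, geoms[[length(geoms)]])
  list(mu = colMeans(FM), sd = pmax(apply(FM, 2, stats::sd), 1e-6))
}

## ---- full network ----------------------------------------------------

## X: [H*W, B*T] with column = (b-1)*T + t; returns probabilities,
## embeddings, attention weights, and caches for backprop.
nn_forward <- function(params, geoms, X, B, T, dropout_mask = NULL,
                       feat_stats = NULL) {
  caches <- list()
  cur <- X
  for (l in seq_along(params$conv)) {
    cv <- conv_forward(cur, params$conv[[l]]$W, params$conv[[l]]$b,
                       geoms[[l]])
    caches[[l]] <- cv
    cur <- cv$out
  }
  geomL <- geoms[[length(geoms)]]
  FM <- gap_forward(cur, geomL)                 # [B*T, D]
  if (!is.null(feat_stats)) {
    FM <- sweep(sweep(FM, 2, feat_stats$mu), 2, feat_stats$sd, "/")
  }
  D <- ncol(FM)
  Fs <- lapply(seq_len(T), function(t) FM[(seq_len(B) - 1) * T + t, ,
                                          drop = FALSE])
  H <- ncol(params$rnn_f$Wh)
  run_rnn <- function(p, order) {
    hs <- vector("list", T)
    h <- matrix(0, B, H)
    for (t in order) {
      h <- tanh(Fs[[t]] %*% p$Wx + h %*% p$Wh +
                  matrix(p$b, B, H, byrow = TRUE))
      hs[[t]] <- h
    }
    hs
  }
  hf <- run_rnn(params$rnn_f, seq_len(T))
  hb <- run_rnn(params$rnn_b, rev(seq_len(T)))
  g <- lapply(seq_len(T), function(t) cbind(hf[[t]], hb[[t]]))
  U <- lapply(g, function(gt) tanh(sweep(gt %*% params$attn$Wa, 2,
                                         params$attn$ba, "+")))
  E <- vapply(U, function(ut) as.vector(ut %*% params$attn$v), numeric(B))
  E <- matrix(E, B, T)
  Emax <- apply(E, 1, max)
  alpha <- exp(E - Emax)
  alpha <- alpha / rowSums(alpha)
  S <- matrix(0, B, 2 * H)
  for (t in seq_len(T)) S <- S + alpha[, t] * g[[t]]
  ## skip connection: the head also sees the plain mean of the frame
  ## features, so the attention/recurrent path refines rather than gates
  ## the frame-level signal
  Fbar <- Reduce(`+`, Fs) / T
  S2 <- cbind(S, Fbar)
  Sd <- if (is.null(dropout_mask)) S2 else S2 * dropout_mask
  z <- as.vector(Sd %*% params$head$w) + params$head$b
  p <- logistic(z)
  list(p = p, S = S2, Sd = Sd, alpha = alpha, g = g, U = U, hf = hf,
       hb = hb, Fs = Fs, FM = FM, conv_caches = caches, B = B, T = T,
       D = D, H = H)
}

nn_backward <- function(params, geoms, fw, X, soft_labels, l2 = 0,
                        dropout_mask = NULL, feat_stats = NULL) {
  B <- fw$B; T <- fw$T; H <- fw$H
  grads <- nn_map(params, function(x) x * 0)
  dz <- (fw$p - soft_labels) / B
  grads$head$w <- crossprod(fw$Sd, matrix(dz)) + l2 * params$head$w
  grads$head$b <- sum(dz)
  dS2 <- matrix(dz) %*% t(params$head$w)
  if (!is.null(dropout_mask)) dS2 <- dS2 * dropout_mask
  dS <- dS2[, seq_len(2 * H), drop = FALSE]
  dFbar <- dS2[, 2 * H + seq_len(fw$D), drop = FALSE]
  dg <- lapply(seq_len(T), function(t) fw$alpha[, t] * dS)
  dalpha <- vapply(seq_len(T), function(t) rowSums(dS * fw$g[[t]]),
                   numeric(B))
  dalpha <- matrix(dalpha, B, T)
  rowdot <- rowSums(fw$alpha * dalpha)
  dE <- fw$alpha * (dalpha - rowdot)
  dWa <- params$attn$Wa * 0; dba <- numeric(length(params$attn$ba))
  dv <- params$attn$v * 0
  for (t in seq_len(T)) {
    de <- dE[, t]
    dv <- dv + as.vector(crossprod(fw$U[[t]], de))
    dU <- outer(de, params$attn$v)
    dpre <- dU * (1 - fw$U[[t]]^2)
    dWa <- dWa + crossprod(fw$g[[t]], dpre)
    dba <- dba + colSums(dpre)
    dg[[t]] <- dg[[t]] + dpre %*% t(params$attn$Wa)
  }
  grads$attn <- list(Wa = dWa + l2 * params$attn$Wa, ba = dba, v = dv)

  dF <- lapply(seq_len(T), function(t) dFbar / T)
  back_rnn <- function(p, hs, order, dh_from_g) {
    gr <- list(Wx = p$Wx * 0, Wh = p$Wh * 0, b = p$b * 0)
    dh_next <- matrix(0, B, H)
    for (t in rev(order)) {
      dh <- dh_from_g(t) + dh_next
      dpre <- dh * (1 - hs[[t]]^2)
      gr$Wx <- gr$Wx + crossprod(fw$Fs[[t]], dpre)
      gr$b <- gr$b + colSums(dpre)
      prev <- which(order == t) - 1
      h_prev <- if (prev >= 1) hs[[order[prev]]] else matrix(0, B, H)
      gr$Wh <- gr$Wh + crossprod(h_prev, dpre)
      dF[[t]] <<- dF[[t]] + dpre %*% t(p$Wx)
      dh_next <- dpre %*% t(p$Wh)
    }
    gr
  }
  grads$rnn_f <- back_rnn(params$rnn_f, fw$hf, seq_len(T),
                          function(t) dg[[t]][, seq_len(H), drop = FALSE])
  grads$rnn_b <- back_rnn(params$rnn_b, fw$hb, rev(seq_len(T)),
                          function(t) dg[[t]][, H + seq_len(H), drop = FALSE])
  grads$rnn_f$Wx <- grads$rnn_f$Wx + l2 * params$rnn_f$Wx
  grads$rnn_b$Wx <- grads$rnn_b$Wx + l2 * params$rnn_b$Wx

  dFM <- matrix(0, B * T, fw$D)
  for (t in seq_len(T)) dFM[(seq_len(B) - 1) * T + t, ] <- dF[[t]]
  if (!is.null(feat_stats)) dFM <- sweep(dFM, 2, feat_stats$sd, "/")
  geomL <- geoms[[length(geoms)]]
  dcur <- gap_backward(dFM, geomL)
  for (l in rev(seq_along(params$conv))) {
    bk <- conv_backward(dcur, fw$conv_caches[[l]], params$conv[[l]]$W,
                        geoms[[l]], need_dx = l > 1)
    grads$conv[[l]]$W <- bk$dW + l2 * params$conv[[l]]$W
    grads$conv[[l]]$b <- bk$db
    if (l > 1) dcur <- bk$dX
  }
  grads
}
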