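# Internal orchestration of the six-branch 1-D CNN.
#
# Convolutional-stage activations are (channels, time * batch) matrices in
# column-major, time-fastest order, so flattening a branch is a zero-copy
# dim change. The layer kernels (convolution as shifted matrix products,
# fused ReLU + batch normalization, max pooling) live in src/ for speed;
# this file owns parameter bookkeeping, the backward sweep, the optimizer,
# and every source of randomness (dropout masks and shuffling draw from
# R's RNG so seeding contracts hold). Gradients are verified against
# numerical differentiation in the test suite.

BN_EPS <- 1e-5
BN_MOMENTUM <- 0.1

# --- parameter initialization (fan-in-scaled normal) ----------------------

init_params <- function(spec) {
  params <- list()
  state <- list()
  he <- function(nr, nc) {
    matrix(stats::rnorm(nr * nc, 0, sqrt(2 / nc)), nr, nc)
  }
  for (b in seq_len(spec$n_branches)) {
    c_in <- 1L
    for (k in seq_len(spec$conv_blocks)) {
      c_out <- spec$filters[k]
      pre <- sprintf("br%d.conv%d", b, k)
      params[[paste0(pre, ".W")]] <- he(c_out, spec$kernel_size * c_in)
      params[[paste0(pre, ".b")]] <- numeric(c_out)
      bn <- sprintf("br%d.bn%d", b, k)
      params[[paste0(bn, ".gamma")]] <- rep(1, c_out)
      params[[paste0(bn, ".beta")]] <- numeric(c_out)
      state[[paste0(bn, ".rm")]] <- numeric(c_out)
      state[[paste0(bn, ".rv")]] <- rep(1, c_out)
      c_in <- c_out
    }
  }
  d_in <- flat_length(spec)
  for (j in seq_along(spec$dense_sizes)) {
    d_out <- spec$dense_sizes[j]
    params[[sprintf("fc%d.W", j)]] <- he(d_out, d_in)
    params[[sprintf("fc%d.b", j)]] <- numeric(d_out)
    params[[sprintf("fcbn%d.gamma", j)]] <- rep(1, d_out)
    params[[sprintf("fcbn%d.beta", j)]] <- numeric(d_out)
    state[[sprintf("fcbn%d.rm", j)]] <- numeric(d_out)
    state[[sprintf("fcbn%d.rv", j)]] <- rep(1, d_out)
    d_in <- d_out
  }
  params[["out.W"]] <- he(1L, d_in)
  params[["out.b"]] <- 0
  list(params = params, state = state)
}

flat_length <- function(spec) {
  t_final <- spec$input_shape[2] %/% (spec$pool_size^spec$conv_blocks)
  spec$n_branches * spec$filters[spec$conv_blocks] * t_final
}

conv_param_names <- function(spec) {
  nm <- character()
  for (b in seq_len(spec$n_branches)) {
    for (k in seq_len(spec$conv_blocks)) {
      nm <- c(nm, sprintf("br%d.conv%d.W", b, k),
              sprintf("br%d.conv%d.b", b, k),
              sprintf("br%d.bn%d.gamma", b, k),
              sprintf("br%d.bn%d.beta", b, k))
    }
  }
  nm
}

conv_state_names <- function(spec) {
  nm <- character()
  for (b in seq_len(spec$n_branches)) {
    for (k in seq_len(spec$conv_blocks)) {
      nm <- c(nm, sprintf("br%d.bn%d.rm", b, k),
              sprintf("br%d.bn%d.rv", b, k))
    }
  }
  nm
}

# --- full forward pass ----------------------------------------------------
# X: (6, T, N) array. train toggles dense dropout + dense BN batch
# statistics; conv_train additionally toggles conv-stage BN (FALSE while
# the convolutional stage is frozen during fine-tuning, so its running
# statistics stay bit-identical).

nn_forward <- function(model, X, train = FALSE, conv_train = train,
                       momentum = BN_MOMENTUM, dropout = train) {
  spec <- model$spec
  P <- model$params
  S <- model$state
  N <- dim(X)[3]
  Tn <- dim(X)[2]
  branch_feats <- vector("list", spec$n_branches)
  branch_caches <- vector("list", spec$n_branches)
  for (b in seq_len(spec$n_branches)) {
    A <- matrix(X[b, , ], 1L, Tn * N)
    T_ <- Tn
    caches <- vector("list", spec$conv_blocks)
    for (k in seq_len(spec$conv_blocks)) {
      pre <- sprintf("br%d.conv%d", b, k)
      bn <- sprintf("br%d.bn%d", b, k)
      bl <- .cpp_block_fwd(A, P[[paste0(pre, ".W")]], P[[paste0(pre, ".b")]],
                           P[[paste0(bn, ".gamma")]], P[[paste0(bn, ".beta")]],
                           S[[paste0(bn, ".rm")]], S[[paste0(bn, ".rv")]],
                           conv_train, BN_EPS, momentum,
                           spec$kernel_size, spec$padding, T_, N)
      S[[paste0(bn, ".rm")]] <- as.numeric(bl$rm)
      S[[paste0(bn, ".rv")]] <- as.numeric(bl$rv)
      caches[[k]] <- list(A_in = A, xhat = bl$xhat, s = bl$s,
                          mask = bl$mask, first = bl$first, T_ = T_)
      A <- bl$out
      T_ <- T_ %/% 2L
    }
    # (C, T_ * N) and (C * T_, N) share column-major layout: zero-copy
    dim(A) <- c(nrow(A) * T_, N)
    branch_feats[[b]] <- A
    branch_caches[[b]] <- caches
  }
  F_ <- do.call(rbind, branch_feats)
  H <- F_
  dense_caches <- vector("list", length(spec$dense_sizes))
  for (j in seq_along(spec$dense_sizes)) {
    Z <- P[[sprintf("fc%d.W", j)]] %*% H + P[[sprintf("fc%d.b", j)]]
    rb <- .cpp_relu_bn_fwd(Z, P[[sprintf("fcbn%d.gamma", j)]],
                           P[[sprintf("fcbn%d.beta", j)]],
                           S[[sprintf("fcbn%d.rm", j)]],
                           S[[sprintf("fcbn%d.rv", j)]], train,
                           BN_EPS, momentum)
    S[[sprintf("fcbn%d.rm", j)]] <- as.numeric(rb$rm)
    S[[sprintf("fcbn%d.rv", j)]] <- as.numeric(rb$rv)
    B <- rb$out
    if (dropout && spec$dropout_rate > 0) {
      keep <- 1 - spec$dropout_rate
      mask <- matrix(stats::runif(length(B)) < keep, nrow(B)) / keep
      D <- B * mask
    } else {
      mask <- NULL
      D <- B
    }
    dense_caches[[j]] <- list(H_in = H, bn = rb, mask = mask)
    H <- D
  }
  z <- P[["out.W"]] %*% H + P[["out.b"]]
  p <- 1 / (1 + exp(-z))
  list(prob = as.numeric(p),
       cache = list(branches = branch_caches,
                    branch_rows = vapply(branch_feats, nrow, integer(1)),
                    dense = dense_caches, H_last = H, p = p, N = N,
                    train = train, conv_train = conv_train),
       state = S)
}

# branch feature matrices before concatenation (eval mode); used to verify
# branch independence
branch_features <- function(model, X) {
  fw <- nn_forward(model, X, train = FALSE)
  rows <- fw$cache$branch_rows
  ends <- cumsum(rows)
  starts <- c(1L, ends[-length(ends)] + 1L)
  F_ <- fw$cache$dense[[1]]$H_in
  lapply(seq_along(rows), function(b) F_[starts[b]:ends[b], , drop = FALSE])
}

bce_loss <- function(p, y) {
  pc <- pmin(pmax(p, 1e-12), 1 - 1e-12)
  -mean(y * log(pc) + (1 - y) * log(1 - pc))
}

# backward pass; returns named gradients. conv = FALSE stops after the
# dense stage (the convolutional gradients are not needed while that
# stage is frozen).
nn_backward <- function(model, cache, y, conv = TRUE) {
  spec <- model$spec
  P <- model$params
  grads <- list()
  N <- cache$N
  dz <- matrix(as.numeric(cache$p) - y, 1L, N) / N
  grads[["out.W"]] <- dz %*% t(cache$H_last)
  grads[["out.b"]] <- sum(dz)
  dH <- crossprod(P[["out.W"]], dz)
  for (j in rev(seq_along(spec$dense_sizes))) {
    dc <- cache$dense[[j]]
    if (!is.null(dc$mask)) dH <- dH * dc$mask
    bb <- .cpp_relu_bn_bwd(dH, dc$bn$xhat, dc$bn$s,
                           P[[sprintf("fcbn%d.gamma", j)]], dc$bn$mask,
                           cache$train)
    grads[[sprintf("fcbn%d.gamma", j)]] <- as.numeric(bb$dgamma)
    grads[[sprintf("fcbn%d.beta", j)]] <- as.numeric(bb$dbeta)
    dZ <- bb$dx
    grads[[sprintf("fc%d.W", j)]] <- dZ %*% t(dc$H_in)
    grads[[sprintf("fc%d.b", j)]] <- rowSums(dZ)
    dH <- crossprod(P[[sprintf("fc%d.W", j)]], dZ)
  }
  if (!conv) return(grads)
  rows <- cache$branch_rows
  ends <- cumsum(rows)
  starts <- c(1L, ends[-length(ends)] + 1L)
  for (b in seq_len(spec$n_branches)) {
    dA <- dH[starts[b]:ends[b], , drop = FALSE]
    caches <- cache$branches[[b]]
    C_last <- spec$filters[spec$conv_blocks]
    dim(dA) <- c(C_last, rows[b] %/% C_last * N)  # zero-copy reshape
    for (k in rev(seq_len(spec$conv_blocks))) {
      cc <- caches[[k]]
      bn <- sprintf("br%d.bn%d", b, k)
      pre <- sprintf("br%d.conv%d", b, k)
      bb <- .cpp_block_bwd(dA, cc$xhat, cc$s, P[[paste0(bn, ".gamma")]],
                           cc$mask, cc$first, cache$conv_train,
                           P[[paste0(pre, ".W")]], cc$A_in,
                           spec$kernel_size, spec$padding, cc$T_, N)
      grads[[paste0(bn, ".gamma")]] <- as.numeric(bb$dgamma)
      grads[[paste0(bn, ".beta")]] <- as.numeric(bb$dbeta)
      grads[[paste0(pre, ".W")]] <- bb$dW
      grads[[paste0(pre, ".b")]] <- as.numeric(bb$db)
      dA <- bb$dA
    }
  }
  grads
}

# --- adaptive-moment optimizer (standard moment coefficients) -------------

adam_init <- function(params, names_upd) {
  list(m = lapply(params[names_upd], function(p) p * 0),
       v = lapply(params[names_upd], function(p) p * 0),
       t = 0L)
}

adam_step <- function(opt, params, grads, names_upd, lr,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  opt$t <- opt$t + 1L
  bc1 <- 1 - beta1^opt$t
  bc2 <- 1 - beta2^opt$t
  for (nm in names_upd) {
    g <- grads[[nm]]
    opt$m[[nm]] <- beta1 * opt$m[[nm]] + (1 - beta1) * g
    opt$v[[nm]] <- beta2 * opt$v[[nm]] + (1 - beta2) * g * g
    params[[nm]] <- params[[nm]] -
      lr * (opt$m[[nm]] / bc1) / (sqrt(opt$v[[nm]] / bc2) + eps)
  }
  list(opt = opt, params = params)
}

global_grad_norm <- function(grads, names_upd) {
  sqrt(sum(vapply(names_upd, function(nm) sum(grads[[nm]]^2), numeric(1))))
}
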