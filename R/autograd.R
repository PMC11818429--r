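# Batched forward pass with cache, analytic backpropagation, and Adam.
#
# Layout: a batch of n embeddings is the matrix P (n x d). Node features
# are kept as a list of M matrices (one n x dim matrix per graph node), so
# every operation is a dense matrix product or an element-wise op over the
# whole batch; explicit loops only run over the M = 5 nodes and the
# attention heads. Gradients are exact (verified against central
# differences in the test suite).

# ---- tree utilities over nested parameter lists -------------------------

tree_map <- function(f, ...) {
  trees <- list(...)
  t1 <- trees[[1L]]
  if (is.list(t1)) {
    out <- lapply(seq_along(t1), function(i) {
      do.call(tree_map, c(list(f), lapply(trees, `[[`, i)))
    })
    names(out) <- names(t1)
    out
  } else if (is.numeric(t1)) {
    do.call(f, trees)
  } else {
    t1  # non-numeric leaves (e.g. combine tags) pass through
  }
}

tree_zero <- function(params) tree_map(function(x) x * 0, params)

tree_sum_sq <- function(params) {
  tot <- 0
  walk <- function(t) {
    if (is.list(t)) lapply(t, walk)
    else if (is.numeric(t)) tot <<- tot + sum(t^2)
    invisible(NULL)
  }
  walk(params)
  tot
}

# ---- batched forward ----------------------------------------------------

sample_dropout_masks <- function(n, M, dim, rate) {
  keep <- 1 - rate
  lapply(seq_len(M), function(i) {
    matrix((stats::runif(n * dim) < keep) / keep, n, dim)
  })
}

model_forward_batch <- function(model, P, training = FALSE, masks = NULL) {
  cfg <- model$config
  par <- model$params
  n <- nrow(P)
  M <- length(cfg$labels)
  if (ncol(P) != cfg$d) {
    stop("embedding matrix has ", ncol(P), " columns but model expects d = ",
         cfg$d)
  }
  H <- lapply(par$enc, function(W) P %*% t(W))       # M x (n x d')
  if (training && cfg$dropout > 0) {
    if (is.null(masks)) {
      masks <- sample_dropout_masks(n, M, cfg$hidden_dim, cfg$dropout)
    }
    H <- lapply(seq_len(M), function(i) H[[i]] * masks[[i]])
  } else {
    masks <- NULL
  }
  cache <- list(P = P, masks = masks, layers = vector("list", cfg$n_layers))
  for (l in seq_len(cfg$n_layers)) {
    layer <- par$layers[[l]]
    K <- length(layer$heads)
    lcache <- list(Hin = H, heads = vector("list", K))
    headU <- vector("list", K)
    for (k in seq_len(K)) {
      hp <- layer$heads[[k]]
      Z <- lapply(H, function(h) h %*% t(hp$W))      # n x dh per node
      S <- vapply(Z, function(z) drop(z %*% hp$a1), numeric(n))
      Tt <- vapply(Z, function(z) drop(z %*% hp$a2), numeric(n))
      S <- matrix(S, n, M); Tt <- matrix(Tt, n, M)
      Epre <- lapply(seq_len(M), function(i) S[, i] + Tt)  # n x M
      alpha <- lapply(Epre, function(Ei) {
        E <- lrelu(Ei, cfg$lrelu_slope)
        w <- exp(E - apply(E, 1L, max))
        w / rowSums(w)
      })
      U <- lapply(seq_len(M), function(i) {
        acc <- 0
        for (j in seq_len(M)) acc <- acc + alpha[[i]][, j] * Z[[j]]
        acc
      })
      headU[[k]] <- U
      lcache$heads[[k]] <- list(Z = Z, Epre = Epre, alpha = alpha)
    }
    A <- lapply(seq_len(M), function(i) {
      if (layer$combine == "concat") {
        do.call(cbind, lapply(headU, `[[`, i))
      } else {
        Reduce(`+`, lapply(headU, `[[`, i)) / K
      }
    })
    H <- lapply(A, elu)
    lcache$A <- A
    cache$layers[[l]] <- lcache
  }
  cache$Hfinal <- H
  logits <- vapply(seq_len(M),
                   function(i) drop(H[[i]] %*% par$Wr[i, ]), numeric(n))
  logits <- matrix(logits, n, M)
  list(probs = sigmoid(logits), logits = logits, cache = cache)
}

# dlogits: n x M gradient of the scalar loss w.r.t. the logits.
# Returns parameter gradients (same tree shape as model$params) and the
# gradient dP w.r.t. the input embedding batch.
model_backward_batch <- function(model, cache, dlogits) {
  cfg <- model$config
  par <- model$params
  M <- length(cfg$labels)
  n <- nrow(dlogits)
  slope <- cfg$lrelu_slope

  gWr <- par$Wr * 0
  dH <- vector("list", M)
  for (i in seq_len(M)) {
    gWr[i, ] <- colSums(dlogits[, i] * cache$Hfinal[[i]])
    dH[[i]] <- outer(dlogits[, i], par$Wr[i, ])
  }

  glayers <- vector("list", cfg$n_layers)
  for (l in rev(seq_len(cfg$n_layers))) {
    layer <- par$layers[[l]]
    lcache <- cache$layers[[l]]
    K <- length(layer$heads)
    dA <- lapply(seq_len(M), function(i) dH[[i]] * elu_grad(lcache$A[[i]]))
    dHin <- lapply(lcache$Hin, function(h) h * 0)
    gheads <- vector("list", K)
    for (k in seq_len(K)) {
      hp <- layer$heads[[k]]
      hc <- lcache$heads[[k]]
      dh_dim <- nrow(hp$W)
      dU <- lapply(seq_len(M), function(i) {
        if (layer$combine == "concat") {
          dA[[i]][, (k - 1L) * dh_dim + seq_len(dh_dim), drop = FALSE]
        } else {
          dA[[i]] / K
        }
      })
      dZ <- lapply(hc$Z, function(z) z * 0)
      dT <- matrix(0, n, M)
      dS <- matrix(0, n, M)
      for (i in seq_len(M)) {
        dalpha <- vapply(seq_len(M),
                         function(j) rowSums(dU[[i]] * hc$Z[[j]]), numeric(n))
        dalpha <- matrix(dalpha, n, M)
        for (j in seq_len(M)) {
          dZ[[j]] <- dZ[[j]] + hc$alpha[[i]][, j] * dU[[i]]
        }
        inner <- rowSums(hc$alpha[[i]] * dalpha)
        dE <- hc$alpha[[i]] * (dalpha - inner)
        dEpre <- dE * lrelu_grad(hc$Epre[[i]], slope)
        dS[, i] <- rowSums(dEpre)
        dT <- dT + dEpre
      }
      ga1 <- numeric(dh_dim)
      ga2 <- numeric(dh_dim)
      for (i in seq_len(M)) {
        dZ[[i]] <- dZ[[i]] + outer(dS[, i], hp$a1) + outer(dT[, i], hp$a2)
        ga1 <- ga1 + colSums(hc$Z[[i]] * dS[, i])
        ga2 <- ga2 + colSums(hc$Z[[i]] * dT[, i])
      }
      gW <- hp$W * 0
      for (j in seq_len(M)) {
        gW <- gW + t(dZ[[j]]) %*% lcache$Hin[[j]]
        dHin[[j]] <- dHin[[j]] + dZ[[j]] %*% hp$W
      }
      gheads[[k]] <- list(W = gW, a1 = ga1, a2 = ga2)
    }
    glayers[[l]] <- list(heads = gheads, combine = layer$combine)
    dH <- dHin
  }

  genc <- vector("list", M)
  dP <- cache$P * 0
  for (i in seq_len(M)) {
    dHm <- if (!is.null(cache$masks)) dH[[i]] * cache$masks[[i]] else dH[[i]]
    genc[[i]] <- t(dHm) %*% cache$P
    dP <- dP + dHm %*% par$enc[[i]]
  }
  list(grads = list(enc = genc, layers = glayers, Wr = gWr), dP = dP)
}

# ---- Adam optimiser ------------------------------------------------------

adam_init <- function(params) {
  list(m = tree_zero(params), v = tree_zero(params), t = 0L)
}

adam_step <- function(params, grads, state, lr = 1e-3, beta1 = 0.9,
                      beta2 = 0.999, eps = 1e-8, weight_decay = 0) {
  if (weight_decay > 0) {
    # decoupled (AdamW-style) shrinkage, applied before the Adam update
    params <- tree_map(function(p) p * (1 - lr * weight_decay), params)
  }
  state$t <- state$t + 1L
  state$m <- tree_map(function(m, g) beta1 * m + (1 - beta1) * g,
                      state$m, grads)
  state$v <- tree_map(function(v, g) beta2 * v + (1 - beta2) * g^2,
                      state$v, grads)
  c1 <- 1 - beta1^state$t
  c2 <- 1 - beta2^state$t
  params <- tree_map(function(p, m, v) p - lr * (m / c1) / (sqrt(v / c2) + eps),
                     params, state$m, state$v)
  list(params = params, state = state)
}
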