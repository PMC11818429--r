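test_that("node encoder matches the per-label linear projection contract", {
  M <- 5L
  # identity projections reproduce the embedding on every node
  W_id <- rep(list(diag(4)), M)
  p <- rnorm(4)
  H <- encode_nodes(p, W_id, dropout_rate = 0, training = FALSE)
  for (i in seq_len(M)) expect_equal(unname(H[i, ]), p)
  # dropout off: training and evaluation agree
  W <- lapply(seq_len(M), function(i) matrix(rnorm(8), 2L, 4L))
  expect_equal(encode_nodes(p, W, 0, training = TRUE),
               encode_nodes(p, W, 0, training = FALSE))
  # shape contract and dimension check
  W128 <- lapply(seq_len(M), function(i) matrix(rnorm(128 * 8), 128L, 8L))
  expect_equal(dim(encode_nodes(rnorm(8), W128)), c(5L, 128L))
  expect_error(encode_nodes(rnorm(3), W128), "expects d = 8")
})

test_that("attention scores evaluate LeakyReLU(a'[Wh_i || Wh_j]) exactly", {
  # zero attention vector kills all scores
  H <- matrix(rnorm(10), 5L, 2L)
  W <- matrix(rnorm(6), 3L, 2L)
  expect_true(all(attention_scores(H, W, rep(0, 6)) == 0))
  # identical node features give a constant score matrix
  Hsame <- matrix(rep(rnorm(2), each = 5L), 5L, 2L)
  e <- attention_scores(Hsame, W, rnorm(6))
  expect_equal(max(e) - min(e), 0)
  # 2-node case against scalar hand evaluation
  H2 <- rbind(c(1, 0), c(0, 1))
  W2 <- rbind(c(2, 0), c(0, 3))
  a <- c(0.5, -1, 0.25, 2)
  got <- attention_scores(H2, W2, a, slope = 0.2)
  lr <- function(x) ifelse(x >= 0, x, 0.2 * x)
  for (i in 1:2) for (j in 1:2) {
    zi <- W2 %*% H2[i, ]; zj <- W2 %*% H2[j, ]
    expect_equal(got[i, j], lr(sum(a * c(zi, zj))))
  }
})

test_that("attention normalization is a neighbourhood-restricted softmax", {
  # equal scores over 5 nodes -> uniform 0.2
  e <- matrix(1.7, 5L, 5L)
  expect_true(all(abs(normalize_attention(e) - 0.2) < 1e-12))
  # scores (0, ln 2) -> weights (1/3, 2/3)
  e2 <- matrix(c(0, log(2)), 1L, 2L)
  expect_equal(drop(normalize_attention(e2, list(1:2))), c(1 / 3, 2 / 3))
  # rows sum to one for arbitrary scores, including extreme magnitudes
  set.seed(5)
  for (r in 1:20) {
    e <- matrix(rnorm(25, sd = 200), 5L, 5L)
    expect_equal(unname(rowSums(normalize_attention(e))), rep(1, 5L))
  }
  expect_error(normalize_attention(e, rep(list(integer(0)), 5L)),
               "at least one node")
})

test_that("graph-attention layer respects convexity and head concatenation", {
  heads <- lapply(1:4, function(k) {
    list(W = matrix(rnorm(32 * 8), 32L, 8L), a1 = rnorm(32), a2 = rnorm(32))
  })
  # identical node features: output is elu(W h) per head, any attention
  h <- rnorm(8)
  H <- matrix(rep(h, each = 5L), 5L, 8L)
  out <- gat_layer(H, heads, "concat")
  expect_equal(dim(out), c(5L, 128L))
  manual <- do.call(cbind, lapply(heads, function(hp) {
    matrix(rep(mfpep:::elu(drop(hp$W %*% h)), each = 5L), 5L, 32L)
  }))
  expect_equal(out, manual)
  # single-node graph: hi' = elu(W hi)
  H1 <- matrix(rnorm(8), 1L, 8L)
  out1 <- gat_layer(H1, heads[1L], "mean")
  expect_equal(drop(out1), mfpep:::elu(drop(heads[[1L]]$W %*% H1[1L, ])))
  # convexity: each head's pre-activation aggregate lies in the convex
  # hull of the transformed neighbour features
  Hr <- matrix(rnorm(40), 5L, 8L)
  hp <- heads[[2L]]
  Z <- Hr %*% t(hp$W)
  alpha <- normalize_attention(attention_scores(Hr, hp$W, c(hp$a1, hp$a2)))
  agg <- alpha %*% Z
  for (c_ in seq_len(ncol(Z))) {
    expect_true(all(agg[, c_] >= min(Z[, c_]) - 1e-12))
    expect_true(all(agg[, c_] <= max(Z[, c_]) + 1e-12))
  }
})

test_that("node classifier is an element-wise sigmoid of per-node logits", {
  H <- matrix(0, 5L, 3L)
  Wr <- matrix(rnorm(15), 5L, 3L)
  expect_equal(unname(classify_nodes(H, Wr)), rep(0.5, 5L))
  H2 <- matrix(1, 5L, 3L)
  Wr2 <- matrix(10, 5L, 3L)
  expect_true(all(classify_nodes(H2, Wr2) > 0.9999))
  # monotone in one node's logit, others untouched
  Wr3 <- matrix(rnorm(15), 5L, 3L)
  H3 <- matrix(rnorm(15), 5L, 3L)
  p0 <- classify_nodes(H3, Wr3)
  H4 <- H3; H4[2L, ] <- H4[2L, ] + Wr3[2L, ]  # move along Wr row: logit up
  p1 <- classify_nodes(H4, Wr3)
  expect_gt(p1[2L], p0[2L])
  expect_equal(p1[-2L], p0[-2L])
})

test_that("forward is deterministic in evaluation mode and matches batch", {
  m <- tiny_model()
  p <- rnorm(9)
  out1 <- forward(m, p)
  out2 <- forward(m, p)
  expect_identical(out1, out2)
  expect_length(out1, 5L)
  expect_named(out1, label_space())
  expect_true(all(out1 > 0 & out1 < 1))
  # single-sample path agrees with the batched path used in training
  batch <- predict_probs(m, matrix(p, 1L))
  expect_equal(unname(drop(batch)), unname(out1))
})

test_that("forward is equivariant under label permutation", {
  m <- tiny_model(seed = 9L)
  p <- rnorm(9)
  base <- unname(forward(m, p))
  set.seed(1)
  for (r in 1:5) {
    perm <- sample(5L)
    mp <- m
    mp$params$enc <- m$params$enc[perm]
    mp$params$Wr <- m$params$Wr[perm, , drop = FALSE]
    expect_equal(unname(forward(mp, p)), base[perm], tolerance = 1e-12)
  }
})

test_that("decide thresholds strictly with optional min-one fallback", {
  expect_identical(decide(c(0.6, 0.7, 0.1, 0.2, 0.3), 0.5),
                   c(1L, 1L, 0L, 0L, 0L))
  expect_identical(decide(c(0.2, 0.3, 0.1, 0.4, 0.2), 0.5, min_one = TRUE),
                   c(0L, 0L, 0L, 1L, 0L))
  expect_identical(decide(c(0.5, 0.5, 0.5, 0.5, 0.5), 0.5), rep(0L, 5L))
  # matrix form mirrors the vector rule row-wise
  pm <- rbind(c(0.6, 0.7, 0.1, 0.2, 0.3), c(0.2, 0.3, 0.1, 0.4, 0.2))
  expect_identical(decide(pm, 0.5, min_one = TRUE),
                   rbind(c(1L, 1L, 0L, 0L, 0L), c(0L, 0L, 0L, 1L, 0L)))
})

test_that("model checkpoints survive a save/load round trip", {
  m <- tiny_model()
  f <- withr::local_tempfile(fileext = ".json")
  save_model(m, f)
  m2 <- load_model(f)
  p <- rnorm(9)
  expect_equal(forward(m2, p), forward(m, p))
  expect_identical(m2$config$labels, m$config$labels)
  expect_error(load_model(tempfile()), "not found")
})
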