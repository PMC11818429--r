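test_that("multi-label BCE matches closed forms and a per-element oracle", {
  # p = 0.5 everywhere: 5 ln 2 per sample regardless of targets
  probs <- matrix(0.5, 3L, 5L)
  expect_equal(multilabel_loss(probs, random_bits(3L)), 5 * log(2))
  # confident correct predictions drive the loss to ~0
  y <- random_bits(4L)
  conf <- ifelse(y == 1L, 1 - 1e-9, 1e-9)
  expect_lt(multilabel_loss(conf, y), 1e-5)
  # brute-force element-wise oracle
  set.seed(13)
  p <- matrix(runif(20, 0.05, 0.95), 4L, 5L)
  yy <- random_bits(4L)
  manual <- 0
  for (i in 1:4) for (j in 1:5) {
    manual <- manual - (yy[i, j] * log(p[i, j]) +
                        (1 - yy[i, j]) * log(1 - p[i, j]))
  }
  expect_equal(multilabel_loss(p, yy), manual / 4, tolerance = 1e-10)
})

test_that("FGM perturbation has radius epsilon and the stated direction", {
  # hand-computed: g = (3, 4), eps = 1 -> (-0.6, -0.8)
  expect_equal(fgm_perturbation(c(3, 4), 1), c(-0.6, -0.8))
  # unit vector scaled by -eps
  u <- c(1, 0, 0)
  expect_equal(fgm_perturbation(u, 0.1), -0.1 * u)
  # norm and positive-scale invariance over random gradients
  set.seed(19)
  for (r in 1:50) {
    g <- rnorm(sample(2:40, 1L))
    eps <- runif(1, 0.01, 2)
    radv <- fgm_perturbation(g, eps)
    expect_equal(sqrt(sum(radv^2)), eps, tolerance = 1e-9)
    expect_equal(fgm_perturbation(5.7 * g, eps), radv, tolerance = 1e-9)
  }
  # matrix form normalises row-wise
  G <- rbind(c(3, 4), c(0.3, -0.4))
  R <- fgm_perturbation(G, 2)
  expect_equal(unname(sqrt(rowSums(R^2))), c(2, 2))
  # degenerate gradients are skipped with a warning
  expect_warning(z <- fgm_perturbation(c(0, 0), 0.5), "skipped")
  expect_equal(z, c(0, 0))
})

test_that("training is reproducible and disabling FGM equals plain BCE", {
  recs <- small_fixture(n_per = 10L, seed = 21L)
  be <- embedding_backend("kmer-test")
  cfg_off <- train_config(epochs = 6L, lr = 5e-3,
                          fgm = fgm_config(enabled = FALSE), seed = 33L)
  fit1 <- train_model(recs, be, cfg_off)
  fit2 <- train_model(recs, be, cfg_off)
  expect_identical(fit1$history, fit2$history)
  expect_identical(fit1$model$params, fit2$model$params)
  # epsilon = 0 takes the identical plain path, bit for bit
  cfg_eps0 <- train_config(epochs = 6L, lr = 5e-3,
                           fgm = fgm_config(epsilon = 0, enabled = TRUE),
                           seed = 33L)
  fit3 <- train_model(recs, be, cfg_eps0)
  expect_identical(fit3$model$params, fit1$model$params)
  expect_equal(fit3$history$loss_init, fit1$history$loss_init)
  expect_equal(fit3$history$loss_adv, fit3$history$loss_init)
  # with FGM on, the adversarial loss exceeds the clean loss
  cfg_on <- train_config(epochs = 6L, lr = 5e-3,
                         fgm = fgm_config(epsilon = 0.05), seed = 33L)
  fit4 <- train_model(recs, be, cfg_on)
  expect_true(all(fit4$history$loss_adv >= fit4$history$loss_init))
  expect_false(identical(fit4$model$params, fit1$model$params))
})

test_that("optimisation reduces the training loss on the motif task", {
  recs <- small_fixture(n_per = 10L, seed = 29L)
  fit <- train_model(recs, embedding_backend("kmer-test"),
                     train_config(epochs = 10L, lr = 5e-3,
                                  fgm = fgm_config(0.05), seed = 1L))
  expect_lt(fit$history$loss_init[10L], fit$history$loss_init[1L])
})

test_that("a missing label class triggers a warning, not a failure", {
  recs <- generate_peptides(synthetic_spec(
    n_per_combination = c(AMP = 12L, ACP = 12L), motif_noise = 0,
    seed = 3L))
  expect_warning(
    fit <- train_model(recs, embedding_backend("kmer-test"),
                       train_config(epochs = 2L, seed = 1L)),
    "no positive training examples")
  expect_s3_class(fit$model, "label_gat_model")
})
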