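# Shared fixtures: tiny models and random multi-label instances.

tiny_model <- function(d = 9L, hidden = 8L, layers = 2L, heads = 2L,
                       final = 3L, dropout = 0, seed = 3L) {
  init_label_gat(d = d, hidden_dim = hidden, n_layers = layers,
                 n_heads = heads, final_dim = final, dropout = dropout,
                 seed = seed)
}

random_bits <- function(n, M = 5L, p = 0.4) {
  matrix(rbinom(n * M, 1L, p), n, M)
}

# A small labelled dataset with one planted motif per single-label class.
small_fixture <- function(n_per = 12L, seed = 7L) {
  generate_peptides(synthetic_spec(
    n_per_combination = stats::setNames(rep(n_per, 5L), label_space()),
    length_range = c(8L, 20L), motif_noise = 0, seed = seed))
}

# Central-difference gradient of a scalar function at x (vector/matrix).
num_grad <- function(f, x, eps = 1e-6, idx = seq_along(x)) {
  g <- numeric(length(idx))
  for (k in seq_along(idx)) {
    i <- idx[k]
    x1 <- x; x1[i] <- x1[i] + eps
    x2 <- x; x2[i] <- x2[i] - eps
    g[k] <- (f(x1) - f(x2)) / (2 * eps)
  }
  g
}
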