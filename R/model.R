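# Label-graph attention model.
#
# One graph node per functional label. A per-label linear projection of the
# peptide embedding p gives node features h_i = dropout(W_i p); multi-head
# graph attention over the fully connected label graph (self-loops
# included) updates node features; a per-node linear map + sigmoid yields
# one probability per label. The network is small (M = 5 nodes), so the
# forward pass and its analytic gradients are implemented directly with
# dense matrix algebra, vectorised over batches.

elu <- function(x) ifelse(x > 0, x, exp(pmin(x, 0)) - 1)
elu_grad <- function(x) ifelse(x > 0, 1, exp(pmin(x, 0)))
lrelu <- function(x, slope) ifelse(x >= 0, x, slope * x)
lrelu_grad <- function(x, slope) ifelse(x >= 0, 1, slope)
sigmoid <- function(x) 1 / (1 + exp(-x))

glorot <- function(nr, nc) {
  lim <- sqrt(6 / (nr + nc))
  matrix(stats::runif(nr * nc, -lim, lim), nr, nc)
}

#' Initialise a label-graph attention model
#'
#' Hidden layers use `n_heads` attention heads of dimension
#' `hidden_dim / n_heads`, concatenated; the final layer uses `n_heads`
#' heads of dimension `final_dim`, averaged. All weights are Glorot-uniform
#' initialised from `seed`; the model carries no bias terms.
#'
#' @param d Input embedding dimension.
#' @param labels Ordered label names (graph nodes); default [label_space()].
#' @param hidden_dim Node feature dimension d' (default 128).
#' @param n_layers Number of graph-attention layers (default 2).
#' @param n_heads Attention heads per layer (default 4); must divide
#'   `hidden_dim`.
#' @param final_dim Per-head dimension of the final (head-averaged) layer.
#' @param dropout Node-encoder dropout rate in \[0, 1).
#' @param lrelu_slope Negative slope of the LeakyReLU used in attention
#'   scoring (default 0.2).
#' @param seed Integer seed for weight initialisation.
#' @param backend Optional backend name tag recorded in the model.
#' @return An object of class `label_gat_model`.
#' @export
init_label_gat <- function(d, labels = label_space(), hidden_dim = 128L,
                           n_layers = 2L, n_heads = 4L, final_dim = 32L,
                           dropout = 0.1, lrelu_slope = 0.2, seed = 1L,
                           backend = "kmer-test") {
  stopifnot(d >= 1L, n_layers >= 1L, n_heads >= 1L,
            dropout >= 0, dropout < 1)
  if (n_layers > 1L && hidden_dim %% n_heads != 0L) {
    stop("hidden_dim must be divisible by n_heads")
  }
  M <- length(labels)
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  enc <- lapply(seq_len(M), function(i) glorot(hidden_dim, d))
  layers <- vector("list", n_layers)
  for (l in seq_len(n_layers)) {
    din <- hidden_dim
    final <- (l == n_layers)
    dh <- if (final) final_dim else hidden_dim %/% n_heads
    heads <- lapply(seq_len(n_heads), function(k) {
      list(W = glorot(dh, din), a1 = stats::runif(dh, -0.3, 0.3),
           a2 = stats::runif(dh, -0.3, 0.3))
    })
    layers[[l]] <- list(heads = heads,
                        combine = if (final) "mean" else "concat")
  }
  Wr <- glorot(M, final_dim)
  structure(list(
    params = list(enc = enc, layers = layers, Wr = Wr),
    config = list(d = d, labels = labels, hidden_dim = hidden_dim,
                  n_layers = n_layers, n_heads = n_heads,
                  final_dim = final_dim, dropout = dropout,
                  lrelu_slope = lrelu_slope, seed = as.integer(seed),
                  backend = backend, schema_version = 1L)),
    class = "label_gat_model")
}

#' @export
print.label_gat_model <- function(x, ...) {
  cfg <- x$config
  cat("<label-graph attention model: ", length(cfg$labels), " labels, d = ",
      cfg$d, ", hidden ", cfg$hidden_dim, ", ", cfg$n_layers, " layer(s) x ",
      cfg$n_heads, " heads>\n", sep = "")
  invisible(x)
}

#' Project a peptide embedding onto the label-graph nodes
#'
#' Row i of the result is `dropout(W_i p)` in training mode and `W_i p` in
#' evaluation mode (inverted dropout: kept entries are rescaled by
#' 1/(1 - rate)).
#'
#' @param p Embedding vector of length d.
#' @param W_list List of M projection matrices, each d' x d.
#' @param dropout_rate Dropout rate in \[0, 1).
#' @param training Logical; dropout is only applied when TRUE.
#' @return M x d' matrix of node features.
#' @export
encode_nodes <- function(p, W_list, dropout_rate = 0, training = FALSE) {
  d <- ncol(W_list[[1L]])
  if (length(p) != d) {
    stop("embedding has length ", length(p), " but encoder expects d = ", d)
  }
  H <- do.call(rbind, lapply(W_list, function(W) drop(W %*% p)))
  if (training && dropout_rate > 0) {
    keep <- 1 - dropout_rate
    mask <- matrix(stats::runif(length(H)) < keep, nrow(H), ncol(H)) / keep
    H <- H * mask
  }
  H
}

#' Unnormalised attention scores for one head
#'
#' `e_ij = LeakyReLU(a^T [W h_i || W h_j])`, evaluated for every ordered
#' node pair over the fully connected label graph.
#'
#' @param H M x din node feature matrix.
#' @param W Head transform matrix (dh x din).
#' @param a Attention vector of length 2*dh (split into source and target
#'   halves).
#' @param slope LeakyReLU negative slope.
#' @return M x M score matrix (row = attending node i, column = node j).
#' @export
attention_scores <- function(H, W, a, slope = 0.2) {
  Z <- H %*% t(W)                      # M x dh
  dh <- ncol(Z)
  stopifnot(length(a) == 2L * dh)
  s <- drop(Z %*% a[seq_len(dh)])      # source-side contribution
  t_ <- drop(Z %*% a[dh + seq_len(dh)])
  lrelu(outer(s, t_, `+`), slope)
}

#' Normalise attention scores over each node's neighbourhood
#'
#' Row-wise softmax restricted to each node's neighbourhood (all nodes by
#' default, matching the fully connected label graph). Numerically stable:
#' the row maximum is subtracted before exponentiation.
#'
#' @param scores M x M score matrix.
#' @param neighborhoods Optional list of integer neighbour sets per node;
#'   every set must be non-empty.
#' @return M x M weight matrix whose rows sum to one (zero outside each
#'   neighbourhood).
#' @export
normalize_attention <- function(scores, neighborhoods = NULL) {
  M <- nrow(scores)
  if (is.null(neighborhoods)) {
    neighborhoods <- rep(list(seq_len(ncol(scores))), M)
  }
  if (any(lengths(neighborhoods) == 0L)) {
    stop("every node must attend to at least one node (itself)")
  }
  W <- matrix(0, M, ncol(scores), dimnames = dimnames(scores))
  for (i in seq_len(M)) {
    ni <- neighborhoods[[i]]
    e <- scores[i, ni]
    w <- exp(e - max(e))
    W[i, ni] <- w / sum(w)
  }
  W
}

#' Apply one multi-head graph-attention layer
#'
#' Per head, node features are transformed, attention-aggregated over the
#' fully connected label graph and passed through the activation; head
#' outputs are concatenated ("concat") or averaged before activation
#' ("mean", used in the final layer).
#'
#' @param H M x din node feature matrix.
#' @param heads List of heads, each `list(W, a1, a2)`.
#' @param combine "concat" or "mean".
#' @param slope LeakyReLU slope for scoring.
#' @return Updated node feature matrix (M rows).
#' @export
gat_layer <- function(H, heads, combine = c("concat", "mean"), slope = 0.2) {
  combine <- match.arg(combine)
  M <- nrow(H)
  outs <- lapply(heads, function(h) {
    e <- attention_scores(H, h$W, c(h$a1, h$a2), slope)
    alpha <- normalize_attention(e)
    alpha %*% (H %*% t(h$W))           # M x dh pre-activation aggregate
  })
  if (combine == "concat") {
    elu(do.call(cbind, outs))
  } else {
    elu(Reduce(`+`, outs) / length(outs))
  }
}

#' Per-node sigmoid classification
#'
#' @param H M x d_final matrix of final node features.
#' @param Wr M x d_final classification weight matrix (row i scores node i).
#' @return Probability vector of length M, in label order.
#' @export
classify_nodes <- function(H, Wr) {
  stopifnot(nrow(H) == nrow(Wr), ncol(H) == ncol(Wr))
  sigmoid(rowSums(H * Wr))
}

#' Forward pass: peptide embedding to per-label probabilities
#'
#' Composition node encoder -> graph-attention layers -> node classifier.
#' Deterministic in evaluation mode (`training = FALSE`).
#'
#' @param model A `label_gat_model`.
#' @param p Embedding vector of length `model$config$d`.
#' @param training Logical; enables node-encoder dropout.
#' @return Named probability vector over the model's labels.
#' @export
forward <- function(model, p, training = FALSE) {
  cfg <- model$config
  H <- encode_nodes(p, model$params$enc, cfg$dropout, training)
  for (layer in model$params$layers) {
    H <- gat_layer(H, layer$heads, layer$combine, cfg$lrelu_slope)
  }
  stats::setNames(classify_nodes(H, model$params$Wr), cfg$labels)
}

#' Threshold probabilities into a label bit vector
#'
#' Strict comparison: a probability exactly at the threshold maps to 0.
#' With `min_one = TRUE` an all-zero decision is replaced by setting the
#' arg-max position.
#'
#' @param probs Probability vector (or n x M matrix).
#' @param threshold Decision threshold (default 0.5).
#' @param min_one Guarantee at least one predicted label.
#' @return Integer bit vector (or matrix) of the same shape.
#' @export
decide <- function(probs, threshold = 0.5, min_one = FALSE) {
  if (is.matrix(probs)) {
    out <- (probs > threshold) * 1L
    if (min_one) {
      none <- rowSums(out) == 0L
      if (any(none)) {
        am <- max.col(probs[none, , drop = FALSE], ties.method = "first")
        out[cbind(which(none), am)] <- 1L
      }
    }
    storage.mode(out) <- "integer"
    return(out)
  }
  bits <- as.integer(probs > threshold)
  if (min_one && all(bits == 0L)) bits[which.max(probs)] <- 1L
  bits
}

#' Predict label probabilities for a batch of embeddings
#'
#' @param model A `label_gat_model`.
#' @param P n x d embedding matrix (rows = peptides).
#' @return n x M probability matrix (column names = labels).
#' @export
predict_probs <- function(model, P) {
  UseMethod("predict_probs")
}

#' @export
predict_probs.label_gat_model <- function(model, P) {
  if (is.null(dim(P))) P <- matrix(P, nrow = 1L)
  out <- model_forward_batch(model, P, training = FALSE)$probs
  colnames(out) <- model$config$labels
  rownames(out) <- rownames(P)
  out
}
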