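# Training: multi-label binary cross-entropy plus FGM adversarial
# perturbation of the input embedding. One optimisation step computes the
# loss and gradients on the clean embeddings, perturbs each embedding by
# epsilon along its (normalised) loss-ascent direction, recomputes loss and
# gradients on the perturbed batch, and applies a single Adam update on the
# summed gradients. The unperturbed embeddings are untouched afterwards.

PROB_FLOOR <- 1e-7

#' Multi-label binary cross-entropy
#'
#' Mean over samples of the sum over labels of
#' \eqn{-[y \log p + (1-y) \log(1-p)]}. Probabilities are clamped away
#' from 0 and 1 by `floor` before taking logarithms.
#'
#' @param probs n x M probability matrix (or vector for one sample).
#' @param targets n x M 0/1 matrix of true labels.
#' @param floor Clamping floor for probabilities (default 1e-7).
#' @return Scalar loss.
#' @export
multilabel_loss <- function(probs, targets, floor = PROB_FLOOR) {
  if (is.null(dim(probs))) probs <- matrix(probs, nrow = 1L)
  if (is.null(dim(targets))) targets <- matrix(targets, nrow = 1L)
  stopifnot(all(dim(probs) == dim(targets)))
  p <- pmin(pmax(probs, floor), 1 - floor)
  y <- targets
  mean(rowSums(-(y * log(p) + (1 - y) * log(1 - p))))
}

#' FGM perturbation of an embedding
#'
#' Given the gradient `g` of the log-likelihood with respect to the
#' embedding, returns \eqn{r_{adv} = -\epsilon\, g / \lVert g\rVert_2},
#' an L2-normalised step of radius epsilon. The direction is invariant to
#' positive rescaling of `g`. A zero or non-finite gradient yields a zero
#' perturbation (the step is skipped) with a warning.
#'
#' @param g Gradient vector (or n x d matrix, perturbed row-wise).
#' @param epsilon Perturbation radius (> 0).
#' @return Perturbation of the same shape as `g` with L2 norm epsilon per
#'   vector (zero where the gradient was degenerate).
#' @export
fgm_perturbation <- function(g, epsilon) {
  stopifnot(is.numeric(epsilon), epsilon > 0)
  if (is.matrix(g)) {
    nrm <- sqrt(rowSums(g^2))
    bad <- !is.finite(nrm) | nrm == 0
    if (any(bad)) {
      warning("zero or non-finite gradient for ", sum(bad),
              " sample(s); perturbation skipped for those rows")
      nrm[bad] <- 1
    }
    r <- -epsilon * g / nrm
    r[bad, ] <- 0
    return(r)
  }
  nrm <- sqrt(sum(g^2))
  if (!is.finite(nrm) || nrm == 0) {
    warning("zero or non-finite gradient; perturbation skipped")
    return(g * 0)
  }
  -epsilon * g / nrm
}

#' FGM configuration
#'
#' @param epsilon Perturbation radius (default 0.5).
#' @param enabled Logical; FALSE reduces training to plain BCE.
#' @return An `fgm_config` list.
#' @export
fgm_config <- function(epsilon = 0.5, enabled = TRUE) {
  stopifnot(is.numeric(epsilon), epsilon >= 0, is.logical(enabled))
  if (enabled && epsilon > 0 && !is.finite(epsilon)) {
    stop("epsilon must be finite")
  }
  structure(list(epsilon = epsilon, enabled = enabled),
            class = "fgm_config")
}

# One optimisation step on a batch. Returns updated params/opt state and
# the loss pair. An epsilon of exactly zero (or enabled = FALSE) takes the
# plain-BCE path, so it reproduces non-adversarial training exactly.
adversarial_step <- function(model, opt_state, P, Y, fgm, lr = 1e-3,
                             weight_decay = 0) {
  training <- model$config$dropout > 0
  fwd <- model_forward_batch(model, P, training = training)
  n <- nrow(P)
  l_init <- multilabel_loss(fwd$probs, Y)
  if (!is.finite(l_init)) {
    stop("non-finite training loss on batch with ids: ",
         paste(utils::head(rownames(P), 5L), collapse = ", "))
  }
  dlogits <- (fwd$probs - Y) / n
  bwd <- model_backward_batch(model, fwd$cache, dlogits)

  if (fgm$enabled && fgm$epsilon > 0) {
    # Eq.-7 convention: g is the gradient of the log-likelihood, i.e. the
    # negative of the loss gradient held in bwd$dP.
    radv <- fgm_perturbation(-bwd$dP, fgm$epsilon)
    P_adv <- P + radv
    fwd_a <- model_forward_batch(model, P_adv, training = training,
                                 masks = fwd$cache$masks)
    l_adv <- multilabel_loss(fwd_a$probs, Y)
    if (!is.finite(l_adv)) {
      stop("non-finite adversarial loss on batch with ids: ",
           paste(utils::head(rownames(P), 5L), collapse = ", "))
    }
    bwd_a <- model_backward_batch(model, fwd_a$cache, (fwd_a$probs - Y) / n)
    grads <- tree_map(`+`, bwd$grads, bwd_a$grads)
  } else {
    l_adv <- l_init
    grads <- bwd$grads
  }

  upd <- adam_step(model$params, grads, opt_state, lr = lr,
                   weight_decay = weight_decay)
  model$params <- upd$params
  list(model = model, opt_state = upd$state,
       loss = list(initial = l_init, adversarial = l_adv, batch_size = n))
}

#' Training configuration
#'
#' @param epochs Number of passes over the training data (default 100).
#' @param lr Adam learning rate (default 1e-3).
#' @param batch_size Mini-batch size (default 64).
#' @param fgm An [fgm_config()].
#' @param val_fraction Fraction of the training records carved out
#'   (group-stratified) for checkpoint selection (default 0.1).
#' @param threshold Decision threshold used for validation metrics.
#' @param weight_decay Decoupled (AdamW-style) weight-decay coefficient
#'   (default 0).
#' @param min_one Apply the at-least-one-label fallback when computing
#'   validation metrics (default FALSE).
#' @param selection Checkpoint-selection rule: "absolute_true" (best
#'   validation absolute true, default), "loss" (lowest validation BCE —
#'   a continuous criterion, less noisy on small validation carve-outs)
#'   or "final" (last epoch).
#' @param seed RNG seed governing shuffling, dropout and the validation
#'   carve-out.
#' @return A `train_config` list.
#' @export
train_config <- function(epochs = 100L, lr = 1e-3, batch_size = 64L,
                         fgm = fgm_config(), val_fraction = 0.1,
                         threshold = 0.5, weight_decay = 0,
                         min_one = FALSE,
                         selection = c("absolute_true", "loss", "final"),
                         seed = 1L) {
  stopifnot(epochs >= 1L, lr > 0, batch_size >= 1L,
            val_fraction >= 0, val_fraction < 1, weight_decay >= 0)
  list(epochs = as.integer(epochs), lr = lr,
       batch_size = as.integer(batch_size), fgm = fgm,
       val_fraction = val_fraction, threshold = threshold,
       weight_decay = weight_decay, min_one = isTRUE(min_one),
       selection = match.arg(selection),
       seed = as.integer(seed))
}

#' Train a label-graph attention model
#'
#' Embeds the training records with `backend`, carves out a
#' group-stratified validation split, and optimises binary cross-entropy
#' (plus the FGM adversarial loss when enabled) with Adam. The returned
#' model carries the parameters of the epoch with the best validation
#' absolute-true score.
#'
#' @param records Training peptide data.frame (see [peptide_set()]).
#' @param backend An [embedding_backend()] used to embed the sequences, or
#'   a precomputed embedding matrix with rownames matching the record ids.
#' @param config A [train_config()].
#' @param model Optional pre-initialised `label_gat_model`; by default one
#'   is initialised from `config$seed`.
#' @return List with `model` (best checkpoint), `history` (per-epoch
#'   data.frame: losses and validation metrics) and `config`.
#' @export
train_model <- function(records, backend = embedding_backend(),
                        config = train_config(), model = NULL) {
  records <- validate_peptides(records)
  if (nrow(records) == 0L) stop("training set is empty")
  if (is.matrix(backend)) {
    P_all <- backend[records$id, , drop = FALSE]
  } else {
    P_all <- embed_peptides(records, backend)
  }
  Y_all <- label_matrix(records)
  empty <- colSums(Y_all) == 0L
  if (any(empty)) {
    warning("no positive training examples for label(s): ",
            paste(label_space()[empty], collapse = ", "))
  }

  if (config$val_fraction > 0 && nrow(records) >= 10L) {
    carve <- split_train_test(records, fraction = 1 - config$val_fraction,
                              seed = config$seed + 1L)
    fit_ids <- carve$train$id
    val_ids <- carve$test$id
  } else {
    fit_ids <- records$id
    val_ids <- records$id
  }
  P_fit <- P_all[fit_ids, , drop = FALSE]
  Y_fit <- Y_all[fit_ids, , drop = FALSE]
  P_val <- P_all[val_ids, , drop = FALSE]
  Y_val <- Y_all[val_ids, , drop = FALSE]

  if (is.null(model)) {
    model <- init_label_gat(d = ncol(P_all), seed = config$seed,
                            backend = if (is.matrix(backend)) "precomputed"
                                      else backend$name)
  }
  opt_state <- adam_init(model$params)

  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(config$seed)

  n <- nrow(P_fit)
  best <- list(score = -Inf, params = model$params, epoch = 0L)
  history <- vector("list", config$epochs)
  for (epoch in seq_len(config$epochs)) {
    ord <- sample.int(n)
    starts <- seq(1L, n, by = config$batch_size)
    l_init <- l_adv <- 0
    for (s in starts) {
      idx <- ord[s:min(s + config$batch_size - 1L, n)]
      step <- adversarial_step(model, opt_state,
                               P_fit[idx, , drop = FALSE],
                               Y_fit[idx, , drop = FALSE],
                               config$fgm, lr = config$lr,
                               weight_decay = config$weight_decay)
      model <- step$model
      opt_state <- step$opt_state
      l_init <- l_init + step$loss$initial * length(idx)
      l_adv <- l_adv + step$loss$adversarial * length(idx)
    }
    val_probs <- model_forward_batch(model, P_val)$probs
    val_pred <- decide(val_probs, config$threshold, min_one = config$min_one)
    rep_ <- multilabel_metrics(Y_val, val_pred)
    val_loss <- multilabel_loss(val_probs, Y_val)
    score <- switch(config$selection,
                    absolute_true = rep_$absolute_true,
                    loss = -val_loss,
                    final = epoch)
    # ties resolve to the later (better-converged) epoch
    if (score >= best$score) {
      best <- list(score = score, params = model$params, epoch = epoch)
    }
    history[[epoch]] <- data.frame(
      epoch = epoch, loss_init = l_init / n, loss_adv = l_adv / n,
      val_loss = val_loss,
      val_absolute_true = rep_$absolute_true, val_accuracy = rep_$accuracy)
  }
  model$params <- best$params
  list(model = model, history = do.call(rbind, history),
       best_epoch = best$epoch, config = config)
}
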