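# Weighted probability-level ensembling of per-backend models. Weights are
# non-negative, normalised to sum one at combination time, and may be
# fitted on a validation set by exhaustive search over a discretised
# weight simplex, maximising absolute true.

#' Construct ensemble weights
#'
#' @param weights Non-negative numeric vector, at least one positive.
#' @param member_tags Optional backend names for the members.
#' @return An `ensemble_weights` object (weights stored unnormalised).
#' @export
ensemble_weights <- function(weights, member_tags = NULL) {
  stopifnot(is.numeric(weights), all(weights >= 0))
  if (all(weights == 0)) stop("at least one ensemble weight must be > 0")
  if (is.null(member_tags)) {
    member_tags <- paste0("member", seq_along(weights))
  }
  stopifnot(length(member_tags) == length(weights))
  structure(list(weights = weights, member_tags = member_tags),
            class = "ensemble_weights")
}

#' Combine member probabilities by weighted mean
#'
#' @param member_probs List of probability vectors or n x M matrices, all
#'   of the same shape.
#' @param weights An [ensemble_weights()] or bare numeric vector.
#' @return Weighted element-wise mean (weights normalised to sum one).
#' @export
combine <- function(member_probs, weights = NULL) {
  stopifnot(length(member_probs) >= 1L)
  if (is.null(weights)) weights <- rep(1, length(member_probs))
  if (inherits(weights, "ensemble_weights")) weights <- weights$weights
  if (length(weights) != length(member_probs)) {
    stop("got ", length(member_probs), " members but ", length(weights),
         " weights")
  }
  if (all(weights == 0)) stop("at least one ensemble weight must be > 0")
  shape <- dim(member_probs[[1L]]) %||% length(member_probs[[1L]])
  for (m in member_probs) {
    if (!identical(dim(m) %||% length(m), shape)) {
      stop("ensemble members disagree in shape")
    }
  }
  w <- weights / sum(weights)
  Reduce(`+`, Map(function(m, wi) m * wi, member_probs, w))
}

simplex_grid <- function(n_members, step) {
  s <- round(1 / step)
  if (n_members == 1L) return(matrix(1, 1L, 1L))
  rec <- function(m, left) {
    if (m == 1L) return(matrix(left, 1L, 1L))
    do.call(rbind, lapply(0:left, function(k) {
      cbind(k, rec(m - 1L, left - k))
    }))
  }
  unname(rec(n_members, s) / s)
}

#' Fit ensemble weights on a validation set
#'
#' Exhaustively searches the weight simplex discretised at `grid_step`
#' (the exact uniform weighting is always included as a candidate),
#' maximising validation absolute true of the thresholded combination.
#' Ties are broken toward the weighting closest to uniform.
#'
#' @param member_probs List of n x M probability matrices on the
#'   validation set, one per member.
#' @param truth n x M 0/1 matrix of validation labels.
#' @param grid_step Grid resolution in (0, 0.5\] (default 0.1).
#' @param threshold Decision threshold (default 0.5).
#' @param member_tags Optional member names.
#' @return An [ensemble_weights()] with attributes `score` (best
#'   validation absolute true) and `n_evaluated` (grid size).
#' @export
fit_weights <- function(member_probs, truth, grid_step = 0.1,
                        threshold = 0.5, member_tags = NULL) {
  stopifnot(length(member_probs) >= 2L, grid_step > 0, grid_step <= 0.5)
  truth <- as_bitmat(truth)
  if (nrow(truth) == 0L) stop("validation set is empty")
  m <- length(member_probs)
  grid <- simplex_grid(m, grid_step)
  uniform <- rep(1 / m, m)
  if (!any(apply(grid, 1L, function(w) all(abs(w - uniform) < 1e-12)))) {
    grid <- rbind(grid, uniform)
  }
  score_of <- function(w) {
    pred <- decide(combine(member_probs, w), threshold)
    multilabel_metrics(truth, pred)$absolute_true
  }
  scores <- apply(grid, 1L, score_of)
  best <- max(scores)
  cand <- which(scores >= best - 1e-12)
  dist_u <- apply(grid[cand, , drop = FALSE], 1L,
                  function(w) sum((w - uniform)^2))
  w_best <- grid[cand[which.min(dist_u)], ]
  out <- ensemble_weights(w_best, member_tags)
  attr(out, "score") <- best
  attr(out, "n_evaluated") <- nrow(grid)
  out
}

#' Bundle trained models into a prediction ensemble
#'
#' @param models List of `label_gat_model` objects.
#' @param weights An [ensemble_weights()] (default uniform).
#' @return A `peptide_ensemble` object usable with [predict_probs()].
#' @export
peptide_ensemble <- function(models, weights = NULL) {
  stopifnot(length(models) >= 1L)
  if (is.null(weights)) {
    weights <- ensemble_weights(
      rep(1, length(models)),
      vapply(models, function(m) m$config$backend, ""))
  }
  structure(list(models = models, weights = weights),
            class = "peptide_ensemble")
}

#' @export
predict_probs.peptide_ensemble <- function(model, P) {
  member <- lapply(model$models, predict_probs, P = P)
  combine(member, model$weights)
}
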