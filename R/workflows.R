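# End-to-end workflows behind the command-line entry point (exec/mfpep):
# simulate, train, predict, evaluate, scan. Each writes its artifact plus
# a manifest describing how to reproduce it.

#' Simulate a synthetic dataset to FASTA
#'
#' @param out Output FASTA path.
#' @param seed RNG seed.
#' @param preset "benchmark" ([default_benchmark_like()]) or "fixture"
#'   ([motif_fixture()]).
#' @return The written records, invisibly.
#' @export
run_simulate <- function(out, seed = 1L, preset = c("benchmark", "fixture")) {
  preset <- match.arg(preset)
  recs <- if (preset == "benchmark") default_benchmark_like(seed)
          else motif_fixture(seed)
  write_peptides(recs, out, format = "fasta")
  write_manifest(out, "simulate",
                 list(seed = as.integer(seed), preset = preset))
  invisible(recs)
}

#' Train a model on a dataset file and save the checkpoint
#'
#' @param input Peptide dataset (FASTA/CSV/TSV, see [read_peptides()]).
#' @param model_out Checkpoint .json path.
#' @param seed RNG seed for split, initialisation and training.
#' @param epochs,lr,batch_size,epsilon,fgm_enabled Training settings (see
#'   [train_config()] and [fgm_config()]).
#' @param backend_name Embedding backend name (default "kmer-test").
#' @return List with the fitted model, history and the held-out test
#'   records, invisibly.
#' @export
run_train <- function(input, model_out, seed = 1L, epochs = 100L, lr = 1e-3,
                      batch_size = 64L, epsilon = 0.5, fgm_enabled = TRUE,
                      backend_name = "kmer-test") {
  recs <- deduplicate(read_peptides(input))
  split <- split_train_test(recs, fraction = 0.8, seed = seed)
  backend <- embedding_backend(backend_name)
  cfg <- train_config(epochs = epochs, lr = lr, batch_size = batch_size,
                      fgm = fgm_config(epsilon = epsilon,
                                       enabled = fgm_enabled),
                      seed = seed)
  fit <- train_model(split$train, backend, cfg)
  save_model(fit$model, model_out)
  write_manifest(model_out, "train",
                 list(seed = as.integer(seed), epochs = epochs, lr = lr,
                      batch_size = batch_size, epsilon = epsilon,
                      fgm_enabled = fgm_enabled, backend = backend_name,
                      best_epoch = fit$best_epoch),
                 inputs = input)
  invisible(list(model = fit$model, history = fit$history,
                 test = split$test))
}

#' Predict label probabilities for a dataset file
#'
#' @param model_path Checkpoint .json from [run_train()].
#' @param input Peptide dataset file.
#' @param out Output predictions TSV.
#' @param threshold Decision threshold.
#' @return The predictions data.frame, invisibly.
#' @export
run_predict <- function(model_path, input, out, threshold = 0.5) {
  model <- load_model(model_path)
  recs <- read_peptides(input)
  backend <- embedding_backend(model$config$backend)
  P <- embed_peptides(recs, backend)
  probs <- predict_probs(model, P)
  write_predictions(recs$id, probs, decide(probs, threshold), out)
  write_manifest(out, "predict",
                 list(threshold = threshold, seed = model$config$seed),
                 inputs = c(model_path, input))
  invisible(read_predictions(out))
}

#' Evaluate predictions against a labelled dataset
#'
#' @param truth_input Labelled peptide dataset file.
#' @param predictions Predictions TSV from [run_predict()].
#' @param out Output JSON report.
#' @param threshold Decision threshold for the binary metrics.
#' @return The report list, invisibly.
#' @export
run_evaluate <- function(truth_input, predictions, out, threshold = 0.5) {
  recs <- read_peptides(truth_input)
  preds <- read_predictions(predictions)
  if (!identical(sort(preds$id), sort(recs$id))) {
    first <- setdiff(union(preds$id, recs$id),
                     intersect(preds$id, recs$id))[1L]
    stop("prediction/truth id mismatch; first offending id: ", first)
  }
  preds <- preds[match(recs$id, preds$id), , drop = FALSE]
  probs <- as.matrix(preds[, paste0("prob_", label_space()), drop = FALSE])
  rep_ <- evaluate_predictions(label_matrix(recs), probs, threshold)
  out_obj <- list(
    n_samples = rep_$multilabel$n_samples,
    multilabel = unclass(rep_$multilabel),
    per_label = lapply(rep_$per_label, function(b) {
      c(unclass(b)[c("sensitivity", "specificity", "accuracy", "mcc",
                     "auc")], list(confusion = as.list(b$confusion)))
    }))
  jsonlite::write_json(out_obj, out, auto_unbox = TRUE, digits = NA,
                       na = "null")
  write_manifest(out, "evaluate", list(threshold = threshold),
                 inputs = c(truth_input, predictions))
  invisible(rep_)
}

#' Scan a peptide by saturation mutagenesis and write the table
#'
#' @param sequence Wild-type peptide sequence.
#' @param model_path Checkpoint .json.
#' @param out Output TSV.
#' @return The `scan_result`, invisibly.
#' @export
run_scan <- function(sequence, model_path, out) {
  model <- load_model(model_path)
  backend <- embedding_backend(model$config$backend)
  res <- scan_peptide(sequence, model, backend)
  scan_report(res, out)
  write_manifest(out, "scan",
                 list(sequence = sequence, seed = model$config$seed),
                 inputs = model_path)
  invisible(res)
}

parse_cli_args <- function(args) {
  if (length(args) == 0L) stop("no subcommand given")
  cmd <- args[[1L]]
  opts <- list()
  i <- 2L
  while (i <= length(args)) {
    a <- args[[i]]
    if (!startsWith(a, "--")) stop("unexpected argument: ", a)
    key <- sub("^--", "", a)
    if (i + 1L > length(args)) stop("missing value for --", key)
    opts[[key]] <- args[[i + 1L]]
    i <- i + 2L
  }
  list(command = cmd, opts = opts)
}

opt_or <- function(opts, key, default) {
  if (!is.null(opts[[key]])) opts[[key]] else default
}

#' Command-line entry point
#'
#' Dispatches the subcommands `simulate`, `train`, `predict`, `evaluate`
#' and `scan` (see the `exec/mfpep` script). Returns the exit status.
#'
#' @param args Character vector of command-line arguments.
#' @return 0 on success (errors propagate to the caller).
#' @export
mfpep_main <- function(args = commandArgs(trailingOnly = TRUE)) {
  parsed <- parse_cli_args(args)
  o <- parsed$opts
  switch(parsed$command,
    simulate = run_simulate(out = o$out,
                            seed = as.integer(opt_or(o, "seed", 1L)),
                            preset = opt_or(o, "preset", "benchmark")),
    train = run_train(input = o$input, model_out = o$model,
                      seed = as.integer(opt_or(o, "seed", 1L)),
                      epochs = as.integer(opt_or(o, "epochs", 100L)),
                      lr = as.numeric(opt_or(o, "lr", 1e-3)),
                      batch_size = as.integer(opt_or(o, "batch-size", 64L)),
                      epsilon = as.numeric(opt_or(o, "epsilon", 0.5)),
                      fgm_enabled = !identical(opt_or(o, "fgm", "on"), "off"),
                      backend_name = opt_or(o, "backend", "kmer-test")),
    predict = run_predict(model_path = o$model, input = o$input,
                          out = o$out,
                          threshold = as.numeric(opt_or(o, "threshold",
                                                        0.5))),
    evaluate = run_evaluate(truth_input = o$truth,
                            predictions = o$predictions, out = o$out,
                            threshold = as.numeric(opt_or(o, "threshold",
                                                          0.5))),
    scan = run_scan(sequence = o$sequence, model_path = o$model,
                    out = o$out),
    stop("unknown subcommand '", parsed$command, "'; expected one of: ",
         "simulate, train, predict, evaluate, scan"))
  invisible(0L)
}
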