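# Text (JSON) serialisation of model checkpoints and ensemble manifests.
# Checkpoints carry a schema version, the label order and all dimensions,
# so a loaded model is usable without any side information.

pack_tree <- function(x) {
  if (is.matrix(x)) {
    list(kind = "matrix", dim = dim(x), data = as.vector(x))
  } else if (is.numeric(x)) {
    list(kind = "vector", data = as.vector(x))
  } else if (is.list(x)) {
    list(kind = "list", names = names(x) %||% character(0),
         items = lapply(x, pack_tree))
  } else {
    list(kind = "scalar", data = x)
  }
}

unpack_tree <- function(x) {
  switch(x$kind,
         matrix = matrix(unlist(x$data), x$dim[[1L]], x$dim[[2L]]),
         vector = as.numeric(unlist(x$data)),
         scalar = unlist(x$data),
         list = {
           items <- lapply(x$items, unpack_tree)
           if (length(x$names) == length(items)) names(items) <- x$names
           items
         })
}

#' Save a model checkpoint as JSON
#'
#' @param model A `label_gat_model`.
#' @param path Output .json file.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "label_gat_model"))
  obj <- list(schema = "mfpep/label_gat_model",
              schema_version = 1L,
              config = model$config,
              params = pack_tree(model$params))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Load a model checkpoint written by [save_model()]
#'
#' @param path Checkpoint .json file.
#' @return A `label_gat_model`.
#' @export
load_model <- function(path) {
  if (!file.exists(path)) stop("model checkpoint not found: ", path)
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (!identical(obj$schema, "mfpep/label_gat_model")) {
    stop("not a model checkpoint: ", path)
  }
  cfg <- obj$config
  cfg$labels <- unlist(cfg$labels)
  for (f in c("d", "hidden_dim", "n_layers", "n_heads", "final_dim",
              "seed", "schema_version")) {
    cfg[[f]] <- as.integer(cfg[[f]])
  }
  for (f in c("dropout", "lrelu_slope")) cfg[[f]] <- as.numeric(cfg[[f]])
  params <- unpack_tree(obj$params)
  structure(list(params = params, config = cfg), class = "label_gat_model")
}

#' Write a run manifest next to an output artifact
#'
#' Records the command, configuration, seed, package version and input
#' file checksums so the artifact is reproducible from the manifest alone.
#'
#' @param out_path The artifact the manifest describes; the manifest is
#'   written to `<out_path>.manifest.json`.
#' @param command Workflow name.
#' @param config List of configuration values (must include the seed).
#' @param inputs Character vector of input file paths to checksum.
#' @return The manifest path, invisibly.
#' @export
write_manifest <- function(out_path, command, config, inputs = character(0)) {
  manifest <- list(
    command = command,
    config = config,
    package = "mfpep",
    version = as.character(utils::packageVersion("mfpep")),
    inputs = lapply(inputs, function(p) {
      list(path = p, md5 = unname(tools::md5sum(p)))
    }),
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  mpath <- paste0(out_path, ".manifest.json")
  jsonlite::write_json(manifest, mpath, auto_unbox = TRUE, digits = NA)
  invisible(mpath)
}
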