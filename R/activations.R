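# Adapter for externally computed layer activations (e.g. deep-network
# layers exported by another toolchain). The container is a directory of
# per-layer CSV matrices plus a JSON manifest of layer names and stimulus
# ids, so it is portable, diffable and reproducible bit-for-bit.

#' Write an activation container
#'
#' Serializes a list of layer [feature_matrix] objects to a directory:
#' one CSV per layer (first column `stimulus_id`, then `feature_0 ...`)
#' plus `manifest.json` listing layer order and stimulus ids.
#'
#' @param layers Named list of [feature_matrix] objects sharing stimulus ids.
#' @param path Directory to create or overwrite.
#' @return `path`, invisibly.
#' @export
write_activation_container <- function(layers, path) {
  stopifnot(is.list(layers), length(layers) >= 1)
  if (is.null(names(layers)) || any(names(layers) == "")) {
    names(layers) <- vapply(layers, function(x) attr(x, "layer_name"),
                            character(1))
  }
  ids <- stimulus_ids(layers[[1]])
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  for (nm in names(layers)) {
    x <- layers[[nm]]
    if (!identical(stimulus_ids(x), ids)) {
      stop("layer '", nm, "' has mismatched stimulus ids")
    }
    df <- data.frame(stimulus_id = ids, unclass(x), check.names = FALSE)
    names(df) <- c("stimulus_id", paste0("feature_", seq_len(ncol(x)) - 1))
    f <- paste0("layer_", nm, ".csv")
    utils::write.csv(df, file.path(path, f), row.names = FALSE)
    files[nm] <- f
  }
  manifest <- list(layers = as.list(files), stimulus_ids = ids)
  jsonlite::write_json(manifest, file.path(path, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' Load one layer from an activation container
#'
#' @param path Container directory written by [write_activation_container()]
#'   (or by any tool following the same layout).
#' @param layer_name Layer to load.
#' @param stimulus_ids Optional id order to align rows to; every requested id
#'   must be present.
#' @return A [feature_matrix].
#' @export
load_activation_matrix <- function(path, layer_name, stimulus_ids = NULL) {
  mf <- file.path(path, "manifest.json")
  if (!file.exists(mf)) stop("no manifest.json under ", path)
  manifest <- jsonlite::read_json(mf, simplifyVector = TRUE)
  if (!layer_name %in% names(manifest$layers)) {
    stop("layer '", layer_name, "' not in container; available: ",
         paste(names(manifest$layers), collapse = ", "))
  }
  df <- utils::read.csv(file.path(path, manifest$layers[[layer_name]]),
                        check.names = FALSE)
  ids <- as.character(df$stimulus_id)
  values <- as.matrix(df[, -1, drop = FALSE])
  if (!is.null(stimulus_ids)) {
    missing <- setdiff(stimulus_ids, ids)
    if (length(missing)) {
      stop("stimulus id(s) absent from container: ",
           paste(missing, collapse = ", "))
    }
    sel <- match(stimulus_ids, ids)
    values <- values[sel, , drop = FALSE]
    ids <- stimulus_ids
  }
  feature_matrix(values, model_name = "external", layer_name = layer_name,
                 stimulus_ids = ids)
}
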