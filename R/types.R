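#' Image stimulus
#'
#' A square intensity grid with values in \[0, 1\] (0 = black, 1 = white),
#' the unit every feature model consumes. Coordinates are row-major with the
#' origin at the top-left: `pixels[i, j]` is image row i (from the top) and
#' column j (from the left).
#'
#' @param pixels Numeric matrix, side x side, values in \[0, 1\]; or a
#'   side x side x 3 array for the color variant.
#' @param variant One of `"color"`, `"grayscale"`, `"silhouette"`.
#' @param label Stimulus identifier.
#' @param class_labels Named character vector of design labels, e.g.
#'   `c(class = "spiky", envelope = "2")`.
#' @return An `image_stimulus` object.
#' @export
image_stimulus <- function(pixels, variant = c("grayscale", "color",
                                               "silhouette"),
                           label = "stimulus", class_labels = character()) {
  variant <- match.arg(variant)
  if (variant == "color") {
    stopifnot(length(dim(pixels)) == 3, dim(pixels)[3] == 3,
              dim(pixels)[1] == dim(pixels)[2])
  } else {
    pixels <- as.matrix(pixels)
    if (nrow(pixels) != ncol(pixels)) stop("image must be square")
  }
  rng <- range(pixels)
  if (rng[1] < -1e-9 || rng[2] > 1 + 1e-9) {
    stop("pixel intensities must lie in [0, 1]")
  }
  structure(list(pixels = pixels, variant = variant, label = label,
                 class_labels = class_labels),
            class = "image_stimulus")
}

#' @export
print.image_stimulus <- function(x, ...) {
  side <- dim(x$pixels)[1]
  cat(sprintf("image_stimulus '%s': %dx%d %s", x$label, side, side,
              x$variant))
  if (length(x$class_labels)) {
    cat(" [", paste(names(x$class_labels), x$class_labels, sep = "=",
                    collapse = ", "), "]", sep = "")
  }
  cat("\n")
  invisible(x)
}

#' Feature matrix for one model layer
#'
#' A stimuli x features activation matrix for a named model layer, the unit
#' RDMs are built from. Rows align with `stimulus_ids`; no undefined entries
#' are allowed.
#'
#' @param values Numeric matrix, stimuli x features.
#' @param model_name,layer_name Model and layer identifiers.
#' @param stimulus_ids Character vector of stimulus ids (defaults to
#'   rownames).
#' @return A `feature_matrix` object (a matrix with metadata attributes).
#' @export
feature_matrix <- function(values, model_name = "model",
                           layer_name = "layer", stimulus_ids = NULL) {
  values <- as.matrix(values)
  if (nrow(values) < 2) stop("a feature matrix needs at least 2 stimuli")
  if (anyNA(values)) stop("feature matrix contains undefined entries")
  if (is.null(stimulus_ids)) {
    stimulus_ids <- rownames(values)
    if (is.null(stimulus_ids)) stimulus_ids <- paste0("s", seq_len(nrow(values)))
  }
  if (length(stimulus_ids) != nrow(values)) {
    stop("one stimulus id per row required")
  }
  stimulus_ids <- unname(stimulus_ids)
  rownames(values) <- stimulus_ids
  structure(values, model_name = model_name, layer_name = layer_name,
            stimulus_ids = stimulus_ids,
            class = c("feature_matrix", "matrix", "array"))
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf("feature_matrix %s/%s: %d stimuli x %d features\n",
              attr(x, "model_name"), attr(x, "layer_name"),
              nrow(x), ncol(x)))
  invisible(x)
}

#' Stimulus ids of a container
#'
#' @param x A [feature_matrix], [rdm], or matrix with rownames.
#' @return Character vector of stimulus ids.
#' @export
stimulus_ids <- function(x) {
  ids <- attr(x, "stimulus_ids")
  if (!is.null(ids)) return(ids)
  ids <- rownames(x)
  if (is.null(ids)) ids <- paste0("s", seq_len(nrow(x)))
  ids
}
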