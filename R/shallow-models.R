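# Shallow feature models: preprocessing, silhouettes, pixelwise, Gabor jet,
# HOG. All extractors are deterministic; feature ordering is row-major from
# the top-left pixel and documented per extractor so saved activations are
# reproducible bit-for-bit.

# Internal: EBImage stores images (x, y); our matrices are (row, col) from
# the top-left, so convert by transposition on the way in and out.
.to_ebimage <- function(m) EBImage::Image(t(m))
.from_ebimage <- function(img) t(EBImage::imageData(img))

#' Load and standardize a raw image
#'
#' Resamples an image to a square grid and min-max rescales intensities into
#' \[0, 1\] (0 = black, 1 = white). Color input is converted to grayscale
#' with fixed Rec.601 luminance weights (0.299, 0.587, 0.114) when
#' `to_gray = TRUE`.
#'
#' @param raw A numeric matrix, a height x width x 3 array, an
#'   [image_stimulus], or a path to a PNG file.
#' @param target_side Output side length in pixels (default 256).
#' @param to_gray Convert color input to grayscale (default `TRUE`).
#' @param label Stimulus identifier for the result.
#' @return An [image_stimulus]. A zero-dynamic-range input is returned as a
#'   constant image carrying attribute `zero_dynamic_range = TRUE`, with a
#'   warning rather than an error.
#' @export
preprocess_image <- function(raw, target_side = 256, to_gray = TRUE,
                             label = "stimulus") {
  if (is.character(raw)) {
    raw <- png::readPNG(raw)
  } else if (inherits(raw, "image_stimulus")) {
    if (is.null(label)) label <- raw$label
    raw <- raw$pixels
  }
  if (length(raw) == 0) stop("empty input image")
  if (length(dim(raw)) == 3) {
    raw <- raw[, , seq_len(min(3, dim(raw)[3])), drop = FALSE]
    if (to_gray) {
      if (dim(raw)[3] == 3) {
        raw <- 0.299 * raw[, , 1] + 0.587 * raw[, , 2] + 0.114 * raw[, , 3]
      } else {
        raw <- raw[, , 1]
      }
    }
  }
  resize_plane <- function(m) {
    if (all(dim(m) == target_side)) return(m)
    .from_ebimage(EBImage::resize(.to_ebimage(m), w = target_side,
                                  h = target_side))
  }
  if (length(dim(raw)) == 3) {
    out <- array(apply(raw, 3, resize_plane), c(target_side, target_side, 3))
  } else {
    out <- resize_plane(as.matrix(raw))
  }
  rng <- range(out)
  zero_range <- rng[1] == rng[2]
  if (zero_range) {
    warning("image has zero dynamic range; returning constant image")
    out[] <- min(max(rng[1], 0), 1)
  } else {
    out <- (out - rng[1]) / (rng[2] - rng[1])
  }
  st <- image_stimulus(out,
                       variant = if (length(dim(out)) == 3) "color"
                                 else "grayscale",
                       label = label)
  attr(st, "zero_dynamic_range") <- zero_range
  st
}

#' Silhouette of a stimulus
#'
#' Binarizes a grayscale stimulus into a filled silhouette: the foreground is
#' the largest connected component of pixels darker than `threshold`, with
#' every interior cavity filled (a donut becomes a disk). Output intensities
#' are exactly 0 (object) and 1 (background).
#'
#' @param stimulus A grayscale [image_stimulus].
#' @param threshold Intensity below which a pixel counts as foreground
#'   (default 0.5).
#' @return An [image_stimulus] with `variant = "silhouette"`.
#' @export
make_silhouette <- function(stimulus, threshold = 0.5) {
  stopifnot(inherits(stimulus, "image_stimulus"))
  if (stimulus$variant == "color") {
    stop("make_silhouette requires a grayscale stimulus")
  }
  m <- stimulus$pixels
  fg <- m < threshold
  if (!any(fg)) {
    stop("no foreground pixels below threshold ", threshold)
  }
  lab <- .from_ebimage(EBImage::bwlabel(.to_ebimage(fg * 1)))
  sizes <- tabulate(lab[lab > 0])
  keep <- lab == which.max(sizes)
  filled <- .from_ebimage(EBImage::fillHull(.to_ebimage(keep * 1))) > 0.5
  out <- matrix(1, nrow(m), ncol(m))
  out[filled] <- 0
  st <- image_stimulus(out, variant = "silhouette", label = stimulus$label,
                       class_labels = stimulus$class_labels)
  st
}

.gray_matrix <- function(stimulus) {
  stopifnot(inherits(stimulus, "image_stimulus"))
  if (stimulus$variant == "color") {
    stop("grayscale stimulus required; run preprocess_image(to_gray = TRUE)")
  }
  stimulus$pixels
}

#' Pixelwise features
#'
#' The raw intensity values of all pixels, flattened in row-major order from
#' the top-left: the baseline model of how much low-level information a raw
#' image carries.
#'
#' @param stimulus A grayscale [image_stimulus].
#' @return Numeric feature vector of length side^2.
#' @export
pixelwise_features <- function(stimulus) {
  m <- .gray_matrix(stimulus)
  as.vector(t(m))
}

# Internal: Gabor-jet filter bank. Complex Gabors with octave-spaced center
# frequencies k = kmax / 2^nu (kmax = pi/2 rad/px) and bandwidth sigma = 2*pi
# (about one octave), numerically mean-corrected so a constant image yields
# exactly zero response. Returns a list of FFTs of wrapped kernels.
.gaborjet_bank <- function(side, n_freqs, n_orients, kmax = pi / 2,
                           sigma = 2 * pi) {
  wrap <- ((seq_len(side) - 1 + side / 2) %% side) - side / 2
  cx <- matrix(wrap, side, side, byrow = TRUE)   # column offset
  cy <- matrix(wrap, side, side)                 # row offset
  r2 <- cx^2 + cy^2
  bank <- vector("list", n_freqs * n_orients)
  for (f in seq_len(n_freqs)) {
    k <- kmax / 2^(f - 1)
    env <- (k^2 / sigma^2) * exp(-k^2 * r2 / (2 * sigma^2))
    for (o in seq_len(n_orients)) {
      phi <- (o - 1) * pi / n_orients
      phase <- k * (cos(phi) * cx + sin(phi) * cy)
      kern <- env * exp(1i * phase)
      kern <- kern - mean(kern)  # exact zero-mean correction
      bank[[(f - 1) * n_orients + o]] <- stats::fft(kern)
    }
  }
  bank
}

#' Gabor-jet features
#'
#' A V1-like model: the image is filtered with complex Gabor wavelets of
#' `n_freqs` octave-spaced spatial frequencies and `n_orients` orientations,
#' and the response magnitudes are read out at the nodes of a regular
#' `grid` x `grid` lattice (node centers of equal image tiles). Feature
#' order is node-major (reading order), then frequency (high to low), then
#' orientation.
#'
#' @param stimulus A grayscale [image_stimulus].
#' @param n_freqs Number of spatial-frequency bands (default 5).
#' @param n_orients Number of orientations spanning 180 degrees (default 8).
#' @param grid Nodes per image side (default 10).
#' @return Nonnegative numeric vector of length
#'   `grid^2 * n_freqs * n_orients` (4000 at the defaults).
#' @export
gaborjet_features <- function(stimulus, n_freqs = 5, n_orients = 8,
                              grid = 10) {
  m <- .gray_matrix(stimulus)
  side <- nrow(m)
  if (grid > side) stop("grid (", grid, ") exceeds image side (", side, ")")
  bank <- .gaborjet_bank(side, n_freqs, n_orients)
  fi <- stats::fft(m)
  nodes <- round((seq_len(grid) - 0.5) * side / grid)
  n_chan <- n_freqs * n_orients
  # magnitude responses per channel, sampled at the lattice nodes
  out <- matrix(0, grid * grid, n_chan)
  for (ch in seq_len(n_chan)) {
    resp <- stats::fft(fi * Conj(bank[[ch]]), inverse = TRUE) / side^2
    mag <- Mod(resp)[nodes, nodes, drop = FALSE]
    out[, ch] <- as.vector(t(mag))  # node-major, reading order
  }
  as.vector(t(out))
}

#' Histogram-of-oriented-gradients features
#'
#' Dalal-Triggs HOG: unsigned gradient orientations (0-180 degrees) are
#' binned into `n_orientations` channels per `cell_px` x `cell_px` cell with
#' linear votes between neighboring bins, then blocks of
#' `cells_per_block` x `cells_per_block` cells (stride one cell) are
#' L2-Hys normalized (clip 0.2) and concatenated in scan order. Captures the
#' distribution of local orientations largely irrespective of position.
#'
#' @param stimulus A grayscale [image_stimulus] whose side is divisible by
#'   `cell_px`.
#' @param n_orientations Orientation bins over 0-180 degrees (default 9).
#' @param cell_px Cell side in pixels (default 8).
#' @param cells_per_block Cells per block side (default 3).
#' @return Numeric vector with values in \[0, 1\], of length
#'   `(cells_per_side - cells_per_block + 1)^2 * cells_per_block^2 *
#'   n_orientations`.
#' @export
hog_features <- function(stimulus, n_orientations = 9, cell_px = 8,
                         cells_per_block = 3) {
  m <- .gray_matrix(stimulus)
  side <- nrow(m)
  if (side %% cell_px != 0) {
    stop("image side (", side, ") not divisible by cell_px (", cell_px, ")")
  }
  n_cells <- side %/% cell_px
  if (n_cells < cells_per_block) {
    stop("fewer cells per side (", n_cells, ") than cells_per_block (",
         cells_per_block, ")")
  }
  gx <- gy <- matrix(0, side, side)
  gx[, 2:(side - 1)] <- (m[, 3:side] - m[, 1:(side - 2)]) / 2
  gy[2:(side - 1), ] <- (m[3:side, ] - m[1:(side - 2), ]) / 2
  mag <- sqrt(gx^2 + gy^2)
  ang <- atan2(gy, gx) %% pi  # unsigned orientation in [0, pi)
  # linear vote between the two nearest bin centers (circular over pi)
  binw <- pi / n_orientations
  pos <- ang / binw - 0.5
  lo <- floor(pos)
  w_hi <- pos - lo
  bin_lo <- (lo %% n_orientations) + 1
  bin_hi <- ((lo + 1) %% n_orientations) + 1
  cell_row <- (row(m) - 1) %/% cell_px + 1
  cell_col <- (col(m) - 1) %/% cell_px + 1
  idx_lo <- cell_row + n_cells * (cell_col - 1) +
    n_cells^2 * (bin_lo - 1)
  idx_hi <- cell_row + n_cells * (cell_col - 1) +
    n_cells^2 * (bin_hi - 1)
  hist <- array(0, c(n_cells, n_cells, n_orientations))
  hist <- hist +
    array(tapply(c(mag * (1 - w_hi), mag * w_hi),
                 factor(c(idx_lo, idx_hi),
                        levels = seq_len(n_cells^2 * n_orientations)),
                 sum, default = 0),
          c(n_cells, n_cells, n_orientations))
  n_blocks <- n_cells - cells_per_block + 1
  out <- numeric(n_blocks^2 * cells_per_block^2 * n_orientations)
  blen <- cells_per_block^2 * n_orientations
  p <- 0L
  for (bi in seq_len(n_blocks)) {
    for (bj in seq_len(n_blocks)) {
      blk <- hist[bi:(bi + cells_per_block - 1),
                  bj:(bj + cells_per_block - 1), , drop = FALSE]
      v <- as.vector(aperm(blk, c(3, 2, 1)))  # cell scan order, bins inner
      nrm <- sqrt(sum(v^2))
      if (nrm > 1e-12) {
        v <- pmin(v / nrm, 0.2)
        nrm2 <- sqrt(sum(v^2))
        v <- v / nrm2
      } else {
        v[] <- 0
      }
      out[(p + 1):(p + blen)] <- v
      p <- p + blen
    }
  }
  out
}

#' Extract a feature matrix from a set of stimuli
#'
#' Applies one of the shallow models to every stimulus and stacks the rows
#' into a [feature_matrix].
#'
#' @param stimuli A list of [image_stimulus] objects.
#' @param model `"pixelwise"`, `"gaborjet"` or `"hog"`.
#' @param ... Passed to the extractor.
#' @return A [feature_matrix] with `model_name = model`.
#' @export
model_features <- function(stimuli, model = c("pixelwise", "gaborjet",
                                              "hog"), ...) {
  model <- match.arg(model)
  fun <- switch(model, pixelwise = pixelwise_features,
                gaborjet = gaborjet_features, hog = hog_features)
  rows <- lapply(stimuli, fun, ...)
  values <- do.call(rbind, rows)
  ids <- vapply(stimuli, function(s) s$label, character(1))
  feature_matrix(values, model_name = model, layer_name = model,
                 stimulus_ids = ids)
}
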