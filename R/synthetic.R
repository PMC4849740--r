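# Synthetic-data generators. They emulate the statistical structure of the
# benchmark stimulus sets and behavioral tasks the analysis pipeline is
# designed for, so every downstream stage can be exercised and validated
# end-to-end without external data. Every generator is a pure function of
# its seed: identical inputs give bit-identical outputs.

# evaluate expr under a local RNG state seeded with `seed`
.with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv()))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  expr
}

#' Stimulus-set design with orthogonal class and envelope dimensions
#'
#' Describes a factorial stimulus set in which perceived class (contour
#' style: spiky, smooth, cuboid) and shape envelope (bounding-box aspect
#' ratio) are manipulated orthogonally, the design used to dissociate
#' perceived shape from physical form.
#'
#' @param n_perceived_classes Number of contour-style classes (>= 2).
#' @param n_envelope_levels Number of aspect-ratio levels (>= 1).
#' @param image_side Image side in pixels (>= 64, default 256).
#' @param variant `"grayscale"` or `"silhouette"` (both render binary
#'   black-on-white; the tag is carried on the stimuli).
#' @param seed Integer seed.
#' @return A `shape_design` list; set size is
#'   `n_perceived_classes * n_envelope_levels`.
#' @export
shape_design <- function(n_perceived_classes = 3, n_envelope_levels = 3,
                         image_side = 256, variant = "grayscale", seed = 1) {
  if (n_perceived_classes < 2) stop("need at least 2 perceived classes")
  if (n_envelope_levels < 1) stop("need at least 1 envelope level")
  if (image_side < 64) {
    stop("image_side ", image_side, " too small to render envelopes; ",
         "minimum is 64")
  }
  structure(list(n_perceived_classes = n_perceived_classes,
                 n_envelope_levels = n_envelope_levels,
                 image_side = image_side, variant = variant, seed = seed),
            class = "shape_design")
}

# triangle wave with period 2*pi/k, peak 1 at theta = 0 (mod period)
.tri_wave <- function(theta, k) {
  ph <- (theta * k / (2 * pi)) %% 1
  1 - 2 * abs(ph - 0.5)
}

# unit contour radius r(theta) per style; all styles are 4-fold symmetric so
# the pre-scaling x and y extents are equal and the bounding-box aspect
# ratio equals the planted anisotropic scaling exactly
.contour_radius <- function(theta, style, variant_k) {
  switch(style,
    spiky  = 0.62 + 0.38 * .tri_wave(theta, 8 + 4 * variant_k),
    smooth = (1 + 0.22 * cos((4 + 4 * variant_k) * theta) +
                0.08 * cos((8 + 4 * variant_k) * theta)) / 1.3,
    stop("unknown contour style: ", style))
}

# rectilinear plus-shape membership test on unit coordinates
.in_plus <- function(x, y, variant_k) {
  w <- 0.5 - 0.08 * variant_k
  (abs(x) <= 1 & abs(y) <= w) | (abs(y) <= 1 & abs(x) <= w)
}

#' Generate a factorial shape stimulus set
#'
#' Renders one binary black-on-white shape per (class, envelope) cell of a
#' [shape_design]. The contour style is determined by the class (spiky =
#' radial star, smooth = low-frequency radial blob, cuboid = rectilinear
#' polygon, cycling with parameter variation for additional classes); the
#' foreground bounding-box aspect ratio is determined by the envelope level
#' (geometrically spaced around 1). Rendering is binary with no
#' anti-aliasing, so pixel-level oracles are exact; the result is
#' deterministic given the design seed.
#'
#' @param design A [shape_design].
#' @return List of [image_stimulus] objects with `class_labels` carrying
#'   `class` and `envelope`.
#' @export
generate_shape_set <- function(design) {
  stopifnot(inherits(design, "shape_design"))
  side <- design$image_side
  L <- design$n_envelope_levels
  ratios <- if (L == 1) 1 else exp(seq(log(0.62), log(1.61), length.out = L))
  styles <- c("spiky", "smooth", "cuboid")
  ax <- (seq_len(side) - (side + 1) / 2) / (side / 2)
  u <- matrix(ax, side, side, byrow = TRUE)   # x, left to right
  v <- matrix(ax, side, side)                 # y, top to bottom
  stimuli <- list()
  for (ci in seq_len(design$n_perceived_classes)) {
    style <- styles[(ci - 1) %% 3 + 1]
    variant_k <- (ci - 1) %/% 3
    for (ei in seq_len(L)) {
      ar <- ratios[ei]
      s <- 0.72
      x <- u / (sqrt(ar) * s)
      y <- v / (s / sqrt(ar))
      if (style == "cuboid") {
        inside <- .in_plus(x, y, variant_k)
      } else {
        r <- sqrt(x^2 + y^2)
        theta <- atan2(y, x)
        inside <- r <= .contour_radius(theta, style, variant_k)
      }
      pixels <- matrix(1, side, side)
      pixels[inside] <- 0
      lab <- sprintf("c%02d_e%02d", ci, ei)
      stimuli[[lab]] <- image_stimulus(
        pixels,
        variant = if (design$variant == "silhouette") "silhouette"
                  else "grayscale",
        label = lab,
        class_labels = c(class = style, class_index = as.character(ci),
                         envelope = as.character(ei)))
    }
  }
  stimuli
}

#' Binary dissimilarity RDM from design labels
#'
#' Reference RDM in which stimuli sharing a label are at distance 0 and all
#' other pairs at distance 1. Used as the planted "perceived" (class) or
#' "category" structure of synthetic designs.
#'
#' @param labels Character vector of labels, one per stimulus.
#' @param stimulus_ids Optional ids (default names of `labels`).
#' @return An [rdm] with metric `"external"` and the labels as strata.
#' @export
label_rdm <- function(labels, stimulus_ids = NULL) {
  if (is.null(stimulus_ids)) {
    stimulus_ids <- names(labels)
    if (is.null(stimulus_ids)) stimulus_ids <- paste0("s", seq_along(labels))
  }
  d <- outer(labels, labels, FUN = function(a, b) as.numeric(a != b))
  strata <- as.character(labels)
  names(strata) <- stimulus_ids
  rdm(d, stimulus_ids = stimulus_ids, metric = "external", strata = strata)
}

#' Simulate an observer panel from a known true RDM
#'
#' Each simulated participant's RDM is the true RDM plus i.i.d. zero-mean
#' Gaussian noise added to the upper-triangle cells, mirrored to keep the
#' matrix symmetric, and clipped at zero; the diagonal stays undefined.
#' This stands in for similarity-arrangement data when calibrating noise
#' ceilings and model-vs-behavior correlations.
#'
#' @param true_rdm An [rdm], the shared perceptual structure.
#' @param noise_sd Nonnegative noise standard deviation (in dissimilarity
#'   units).
#' @param n_participants Number of simulated observers (>= 1).
#' @param seed Integer seed.
#' @return List of [rdm] objects, one per participant.
#' @export
simulate_observer_rdms <- function(true_rdm, noise_sd = 0.3,
                                   n_participants = 8, seed = 1) {
  if (noise_sd < 0) stop("noise_sd must be nonnegative")
  if (n_participants < 1) stop("need at least one participant")
  m <- as.matrix(true_rdm)
  n <- nrow(m)
  ids <- stimulus_ids(true_rdm)
  ut <- upper.tri(m)
  .with_seed(seed, {
    lapply(seq_len(n_participants), function(p) {
      noisy <- m
      noisy[ut] <- pmax(0, m[ut] + stats::rnorm(sum(ut), 0, noise_sd))
      noisy[lower.tri(noisy)] <- t(noisy)[lower.tri(noisy)]
      rdm(noisy, stimulus_ids = ids, metric = "external",
          strata = attr(true_rdm, "strata"))
    })
  })
}

# nearest correlation-like PSD matrix with unit diagonal (eigenvalue clip)
.psd_corr <- function(C) {
  e <- eigen(C, symmetric = TRUE)
  vals <- pmax(e$values, 1e-8)
  C2 <- e$vectors %*% (vals * t(e$vectors))
  d <- sqrt(diag(C2))
  C2 / tcrossprod(d)
}

#' Simulate layer activations with a planted physical-to-perceived mix
#'
#' Generates one feature matrix per layer such that the layer's
#' correlation-distance RDM tracks a weighted blend of two reference RDMs:
#' weight `w` of "perceived" structure against `1 - w` of "physical"
#' structure. A monotone increasing weight plan emulates the layer-wise
#' crossover from physical to perceived shape observed across deep-network
#' depth. References are z-scored over their upper triangles before
#' blending so neither scale dominates; features are drawn from a Gaussian
#' whose row-correlation matrix realizes the blended target (projected to
#' the nearest valid correlation matrix).
#'
#' @param mix_weights Numeric vector of perceived-structure weights in
#'   \[0, 1\], one per layer (monotone increasing by convention; empty gives
#'   an empty list).
#' @param rdm_physical,rdm_perceived Reference [rdm]s on the same stimuli.
#' @param n_features Features per layer (>= number of stimuli).
#' @param noise_sd Feature noise standard deviation.
#' @param seed Integer seed.
#' @return List of [feature_matrix] objects named `layer_1 ...`, each
#'   carrying its mix weight as attribute `mix_weight`.
#' @export
simulate_layer_features <- function(mix_weights, rdm_physical, rdm_perceived,
                                    n_features = 1000, noise_sd = 0,
                                    seed = 1) {
  if (length(mix_weights) == 0) return(list())
  if (any(mix_weights < 0 | mix_weights > 1)) {
    stop("mix weights must lie in [0, 1]")
  }
  a <- as.matrix(rdm_physical); b <- as.matrix(rdm_perceived)
  if (!all(dim(a) == dim(b))) {
    stop("reference RDM size mismatch: ", nrow(a), " vs ", nrow(b))
  }
  n <- nrow(a)
  if (n_features < n) stop("n_features must be at least the stimulus count")
  ids <- stimulus_ids(rdm_physical)
  zs <- function(m) {
    u <- upper_tri(m)
    (m - mean(u)) / stats::sd(u)
  }
  za <- zs(a); zb <- zs(b)
  out <- vector("list", length(mix_weights))
  for (l in seq_along(mix_weights)) {
    w <- mix_weights[l]
    zmix <- (1 - w) * za + w * zb
    C <- -0.3 * zmix
    C[C > 0.8] <- 0.8; C[C < -0.8] <- -0.8
    diag(C) <- 1
    C <- .psd_corr(C)
    R <- chol(C)
    X <- .with_seed(as.integer(seed) + l, {
      Z <- matrix(stats::rnorm(n * n_features), n, n_features)
      Y <- crossprod(R, Z)
      if (noise_sd > 0) Y <- Y + matrix(stats::rnorm(n * n_features,
                                                     0, noise_sd),
                                        n, n_features)
      Y
    })
    fm <- feature_matrix(X, model_name = "synthetic",
                         layer_name = paste0("layer_", l),
                         stimulus_ids = ids)
    attr(fm, "mix_weight") <- w
    out[[l]] <- fm
  }
  names(out) <- paste0("layer_", seq_along(mix_weights))
  out
}

#' Generate feature triplets with planted non-accidental structure
#'
#' Builds base/NAP-variant/metric-variant feature triplets mirroring the
#' geon benchmark's conservative design: in raw (linear) feature space the
#' NAP variant sits *closer* to the base (`d_nap_linear <= d_metric_linear`),
#' yet the NAP displacement is concentrated in a designated diagnostic
#' subspace (the first `ceil(n_features / 10)` coordinates) whose
#' amplification by `perceptual_gain` reverses the ordering — emulating a
#' representation with heightened sensitivity to non-accidental properties.
#' The metric displacement lies in the complementary subspace and is
#' unaffected by the gain.
#'
#' @param n_triplets Number of triplets (default 22).
#' @param d_nap_linear,d_metric_linear Planted Euclidean displacement norms,
#'   both positive with `d_nap_linear <= d_metric_linear`.
#' @param perceptual_gain Diagnostic-subspace amplification factor (>= 1),
#'   stored on the set and applied by [apply_perceptual_gain()].
#' @param n_features Feature dimensionality (default 100).
#' @param seed Integer seed.
#' @return A `triplet_set`: matrices `base`, `nap`, `metric`
#'   (n_triplets x n_features), `diagnostic_dims`, `perceptual_gain`,
#'   `triplet_ids`.
#' @export
generate_triplet_features <- function(n_triplets = 22, d_nap_linear = 1,
                                      d_metric_linear = 2,
                                      perceptual_gain = 5,
                                      n_features = 100, seed = 1) {
  if (d_nap_linear <= 0 || d_metric_linear <= 0) {
    stop("planted distances must be positive")
  }
  if (d_nap_linear > d_metric_linear) {
    stop("planted design requires d_nap_linear <= d_metric_linear")
  }
  if (perceptual_gain < 1) stop("perceptual_gain must be >= 1")
  k <- ceiling(n_features / 10)
  .with_seed(seed, {
    base <- matrix(stats::rnorm(n_triplets * n_features), n_triplets)
    unit_rows <- function(m) m / sqrt(rowSums(m^2))
    dn <- matrix(0, n_triplets, n_features)
    dn[, seq_len(k)] <- unit_rows(matrix(stats::rnorm(n_triplets * k),
                                         n_triplets)) * d_nap_linear
    dm <- matrix(0, n_triplets, n_features)
    dm[, (k + 1):n_features] <-
      unit_rows(matrix(stats::rnorm(n_triplets * (n_features - k)),
                       n_triplets)) * d_metric_linear
    structure(list(base = base, nap = base + dn, metric = base + dm,
                   diagnostic_dims = seq_len(k),
                   perceptual_gain = perceptual_gain,
                   triplet_ids = sprintf("t%02d", seq_len(n_triplets))),
              class = "triplet_set")
  })
}

#' Amplify the diagnostic subspace of a triplet set
#'
#' Multiplies the diagnostic coordinates of every member (base, NAP, metric)
#' by `gain`, modeling perceptual magnification of non-accidental feature
#' differences. Distances within the complementary subspace are unchanged.
#'
#' @param triplets A `triplet_set`.
#' @param gain Amplification factor (default: the set's stored
#'   `perceptual_gain`).
#' @return A new `triplet_set`.
#' @export
apply_perceptual_gain <- function(triplets, gain = triplets$perceptual_gain) {
  stopifnot(inherits(triplets, "triplet_set"))
  k <- triplets$diagnostic_dims
  out <- triplets
  for (part in c("base", "nap", "metric")) {
    out[[part]][, k] <- out[[part]][, k] * gain
  }
  out
}

#' Simulate per-item naming responses
#'
#' Draws a participants-by-items binary accuracy table with each response an
#' independent Bernoulli draw at the item's success probability, a stand-in
#' for object-naming data.
#'
#' @param item_difficulties Per-item success probabilities in \[0, 1\].
#' @param n_participants Number of simulated participants.
#' @param seed Integer seed.
#' @return Binary matrix (participants x items) with item names as colnames.
#' @export
simulate_naming <- function(item_difficulties, n_participants = 10,
                            seed = 1) {
  p <- as.numeric(item_difficulties)
  if (any(p < 0 | p > 1)) stop("item difficulties must lie in [0, 1]")
  if (n_participants < 1) stop("need at least one participant")
  .with_seed(seed, {
    m <- matrix(stats::rbinom(n_participants * length(p), 1,
                              rep(p, each = n_participants)),
                nrow = n_participants)
    colnames(m) <- if (!is.null(names(item_difficulties)))
      names(item_difficulties) else paste0("item", seq_along(p))
    rownames(m) <- paste0("p", seq_len(n_participants))
    m
  })
}
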