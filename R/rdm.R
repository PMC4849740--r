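#' Representational dissimilarity matrix (RDM)
#'
#' An `rdm` is a symmetric stimulus-by-stimulus matrix of pairwise
#' dissimilarities with an *undefined* diagonal (stored as `NA` and excluded
#' from every statistic), the central object of representational similarity
#' analysis.
#'
#' @param values Square numeric matrix of dissimilarities. The diagonal is
#'   forced to `NA`; off-diagonal entries must be nonnegative and, under the
#'   correlation metric, no larger than 2.
#' @param stimulus_ids Character vector of stimulus identifiers, one per row.
#' @param metric Dissimilarity metric the values were computed with:
#'   `"correlation"` (one minus Pearson correlation between feature rows) or
#'   `"normalized_euclidean"` (Euclidean distance between unit-norm feature
#'   rows). `"external"` marks matrices imported from behavioral data.
#' @param strata Optional named character vector mapping each stimulus id to a
#'   stratum label, used by stratified bootstrap resampling.
#'
#' @return An object of class `rdm`: the values matrix with attributes
#'   `stimulus_ids`, `metric` and `strata`.
#' @seealso [compute_rdm()], [rdm_correlation()], [mds_embed()]
#' @export
rdm <- function(values, stimulus_ids = NULL,
                metric = c("correlation", "normalized_euclidean", "external"),
                strata = NULL) {
  metric <- match.arg(metric)
  values <- as.matrix(values)
  n <- nrow(values)
  if (n != ncol(values)) {
    stop("RDM must be square, got ", n, " x ", ncol(values))
  }
  if (is.null(stimulus_ids)) {
    stimulus_ids <- rownames(values)
    if (is.null(stimulus_ids)) stimulus_ids <- paste0("s", seq_len(n))
  }
  if (length(stimulus_ids) != n) {
    stop("length(stimulus_ids) must equal nrow(values)")
  }
  stimulus_ids <- unname(stimulus_ids)
  diag(values) <- NA_real_
  off <- values[row(values) != col(values)]
  if (any(!is.na(off) & off < -1e-12)) {
    stop("RDM off-diagonal values must be nonnegative")
  }
  if (metric == "correlation" && any(!is.na(off) & off > 2 + 1e-12)) {
    stop("correlation-metric dissimilarities cannot exceed 2")
  }
  asym <- max(abs(values - t(values)), na.rm = TRUE)
  if (isTRUE(asym > 1e-9)) {
    stop("RDM must be symmetric (max asymmetry ", signif(asym, 3), ")")
  }
  dimnames(values) <- list(stimulus_ids, stimulus_ids)
  if (!is.null(strata)) {
    if (is.null(names(strata))) names(strata) <- stimulus_ids
    strata <- as.character(strata[stimulus_ids])
    names(strata) <- stimulus_ids
  }
  structure(values,
            stimulus_ids = stimulus_ids, metric = metric, strata = strata,
            class = c("rdm", "matrix", "array"))
}

#' @export
print.rdm <- function(x, ...) {
  cat(sprintf("RDM: %d stimuli, metric = %s%s\n",
              nrow(x), attr(x, "metric"),
              if (is.null(attr(x, "strata"))) "" else ", stratified"))
  print(round(unclass(x), 3), ...)
  invisible(x)
}

#' Strictly-upper-triangle vector of an RDM
#'
#' Returns the values above the diagonal in column-major order; the undefined
#' diagonal is never included. All RDM-to-RDM statistics operate on this
#' vector.
#'
#' @param x An [rdm] or plain square matrix.
#' @return Numeric vector of length n(n-1)/2.
#' @export
upper_tri <- function(x) {
  x <- as.matrix(x)
  x[upper.tri(x, diag = FALSE)]
}

#' Build an RDM from a feature matrix
#'
#' Computes all pairwise dissimilarities between the rows (stimuli) of a
#' feature matrix. Under the correlation metric the dissimilarity between
#' stimuli is one minus the Pearson correlation of their feature vectors,
#' so values lie in \[0, 2\]. The normalized Euclidean metric first scales
#' each feature row to unit norm, removing overall activation magnitude,
#' then takes Euclidean distances.
#'
#' @param features A [feature_matrix] or plain numeric matrix
#'   (stimuli x features, at least 2 of each).
#' @param metric `"correlation"` or `"normalized_euclidean"`.
#' @param strata Optional stratum labels, passed to [rdm()].
#' @return An [rdm].
#' @examples
#' x <- matrix(rnorm(12), nrow = 3, dimnames = list(c("a", "b", "c"), NULL))
#' compute_rdm(x)
#' @export
compute_rdm <- function(features,
                        metric = c("correlation", "normalized_euclidean"),
                        strata = NULL) {
  metric <- match.arg(metric)
  ids <- stimulus_ids(features)
  x <- as.matrix(features)
  if (nrow(x) < 2 || ncol(x) < 2) {
    stop("need at least 2 stimuli and 2 features, got ",
         nrow(x), " x ", ncol(x))
  }
  if (metric == "correlation") {
    sds <- apply(x, 1, stats::sd)
    if (any(sds == 0)) {
      stop("constant feature row(s): correlation distance undefined for ",
           paste(ids[sds == 0], collapse = ", "))
    }
    d <- 1 - stats::cor(t(x))
    d[d < 0] <- 0  # guard tiny negative rounding of 1 - cor
  } else {
    norms <- sqrt(rowSums(x^2))
    if (any(norms == 0)) {
      stop("zero-norm feature row(s): normalized Euclidean undefined for ",
           paste(ids[norms == 0], collapse = ", "))
    }
    xn <- x / norms
    d <- as.matrix(stats::dist(xn))
  }
  rdm(d, stimulus_ids = ids, metric = metric, strata = strata)
}

#' Correlate two RDMs over their upper triangles
#'
#' Pearson correlation (optionally Spearman) of the strictly-upper-triangle
#' vectors of two matched RDMs. The undefined diagonal never enters; cells
#' undefined in either matrix (as arise from duplicate stimuli under
#' bootstrap resampling) are dropped pairwise.
#'
#' @param a,b [rdm] objects (or square matrices) of the same size and
#'   stimulus order.
#' @param method `"pearson"` (default) or `"spearman"`.
#' @return A single correlation value.
#' @export
rdm_correlation <- function(a, b, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  a <- as.matrix(a); b <- as.matrix(b)
  if (!all(dim(a) == dim(b))) {
    stop("RDM size mismatch: ", nrow(a), " vs ", nrow(b))
  }
  ua <- upper_tri(a); ub <- upper_tri(b)
  keep <- !is.na(ua) & !is.na(ub)
  ua <- ua[keep]; ub <- ub[keep]
  if (length(ua) < 2) stop("fewer than 2 defined upper-triangle cells")
  if (stats::sd(ua) == 0 || stats::sd(ub) == 0) {
    stop("zero variance in an upper triangle: correlation undefined")
  }
  stats::cor(ua, ub, method = method)
}

#' Consistency between two accuracy vectors
#'
#' One minus the normalized squared Euclidean distance,
#' `1 - sum((x - y)^2) / n`, between two accuracy vectors with entries in
#' \[0, 1\] (binary for a single rater, means for a group). On binary input
#' this equals one minus the Matching distance: 1 means identical response
#' patterns, 0.5 means agreement on half the items, 0 maximal disagreement.
#' Unlike a correlation it remains informative when accuracy is near ceiling
#' and variance is low.
#'
#' @param x,y Numeric vectors of equal length with values in \[0, 1\].
#' @return Consistency in \[0, 1\].
#' @examples
#' consistency(c(1, 1, 0, 0), c(1, 0, 1, 0))  # 0.5
#' @export
consistency <- function(x, y) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) != length(y)) {
    stop("length mismatch: ", length(x), " vs ", length(y))
  }
  if (length(x) == 0) stop("empty accuracy vectors")
  if (any(x < 0 | x > 1 | y < 0 | y > 1)) {
    stop("accuracy values must lie in [0, 1]")
  }
  1 - sum((x - y)^2) / length(x)
}

#' Classical multidimensional scaling of an RDM
#'
#' Torgerson double-centering MDS via [stats::cmdscale()], giving a
#' deterministic low-dimensional embedding for visualizing representational
#' geometry. Axis orientation is fixed by requiring the first nonzero
#' loading of each axis to be positive, so repeated calls are bit-identical.
#'
#' @param x An [rdm].
#' @param n_dims Number of embedding dimensions, less than the number of
#'   stimuli.
#' @return Numeric matrix (stimuli x n_dims) with stimulus ids as rownames.
#' @export
mds_embed <- function(x, n_dims = 2) {
  m <- as.matrix(x)
  n <- nrow(m)
  if (n_dims >= n) stop("n_dims must be smaller than the number of stimuli")
  diag(m) <- 0
  coords <- stats::cmdscale(stats::as.dist(m), k = n_dims)
  for (j in seq_len(ncol(coords))) {
    nz <- which(abs(coords[, j]) > 1e-12)
    if (length(nz) && coords[nz[1], j] < 0) coords[, j] <- -coords[, j]
  }
  rownames(coords) <- rownames(m)
  colnames(coords) <- paste0("dim_", seq_len(ncol(coords)))
  coords
}

#' Average a stack of participant RDMs
#'
#' Cellwise mean across participants; the diagonal stays undefined.
#'
#' @param stack A list of matched [rdm] objects (one per participant).
#' @return An [rdm] with metric `"external"`.
#' @export
mean_rdm <- function(stack) {
  stopifnot(length(stack) >= 1)
  ids <- attr(stack[[1]], "stimulus_ids")
  arr <- vapply(stack, as.matrix, matrix(0, length(ids), length(ids)))
  rdm(apply(arr, c(1, 2), mean), stimulus_ids = ids, metric = "external",
      strata = attr(stack[[1]], "strata"))
}
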