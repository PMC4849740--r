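# Bootstrap inference: percentile CIs for accuracies and RDM correlations,
# stratified stimulus resampling, a paired-samples group test on bootstrap
# replicates, and noise-ceiling estimation. All operations are
# seed-deterministic and persist their replicate distributions so figures
# and p-values are exactly reproducible.

#' Bootstrap result container
#'
#' @param point Point estimate on the full data.
#' @param distribution Numeric vector of replicate values.
#' @param n_iter Number of bootstrap iterations.
#' @param seed Seed used for resampling.
#' @param extra Optional named list of extra fields (e.g. resample logs).
#' @return A `bootstrap_result` with 95% percentile CI (`ci_low` = 2.5th,
#'   `ci_high` = 97.5th percentile of the replicates).
#' @export
bootstrap_result <- function(point, distribution, n_iter, seed,
                             extra = list()) {
  qs <- stats::quantile(distribution, c(0.025, 0.975), na.rm = TRUE,
                        names = FALSE)
  structure(c(list(point = point, ci_low = qs[1], ci_high = qs[2],
                   n_iter = n_iter, seed = seed,
                   distribution = distribution), extra),
            class = "bootstrap_result")
}

#' @export
print.bootstrap_result <- function(x, ...) {
  cat(sprintf("bootstrap: %.4f, 95%% CI [%.4f, %.4f] (%d iterations)\n",
              x$point, x$ci_low, x$ci_high, x$n_iter))
  invisible(x)
}

#' Bootstrap CI for a mean accuracy
#'
#' Resamples a vector of correct/incorrect (1/0) responses with replacement
#' and recomputes the mean at each iteration; the 95% CI is the 2.5 and
#' 97.5 percentiles of the replicate means.
#'
#' @param responses Binary (0/1) response vector.
#' @param n_iter Iterations (default 1000).
#' @param seed Integer seed.
#' @return A [bootstrap_result].
#' @export
bootstrap_accuracy_ci <- function(responses, n_iter = 1000, seed = 1) {
  responses <- as.numeric(responses)
  if (length(responses) == 0) stop("empty response vector")
  if (!all(responses %in% c(0, 1))) stop("responses must be binary 0/1")
  n <- length(responses)
  reps <- .with_seed(seed, {
    vapply(seq_len(n_iter),
           function(i) mean(responses[sample.int(n, n, replace = TRUE)]),
           numeric(1))
  })
  bootstrap_result(mean(responses), reps, n_iter, seed)
}

# draw one with-replacement stimulus resample, within strata if given
.resample_indices <- function(n, strata = NULL) {
  if (is.null(strata)) return(sample.int(n, n, replace = TRUE))
  idx <- integer(n)
  for (s in unique(strata)) {
    members <- which(strata == s)
    idx[members] <- members[sample.int(length(members), length(members),
                                       replace = TRUE)]
  }
  idx
}

.check_strata <- function(a, b, stratified) {
  if (!stratified) return(NULL)
  strata <- attr(a, "strata")
  if (is.null(strata)) stop("stratified resampling requested but RDM carries no strata")
  if (!is.null(b) && !identical(strata, attr(b, "strata"))) {
    stop("stratified resampling requires identical strata on both RDMs")
  }
  sizes <- table(strata)
  if (any(sizes < 2)) {
    stop("stratum of size 1 cannot be resampled: ",
         paste(names(sizes)[sizes < 2], collapse = ", "))
  }
  as.character(strata)
}

# correlation of the defined upper-triangle cells of two index-resampled
# RDMs; cells whose row and column index the same original stimulus are
# undefined (the resampled analogue of the undefined diagonal)
.resampled_correlation <- function(a, b, idx, method) {
  a2 <- a[idx, idx]; b2 <- b[idx, idx]
  dup <- outer(idx, idx, "==")
  a2[dup] <- NA_real_; b2[dup] <- NA_real_
  tryCatch(rdm_correlation(a2, b2, method = method),
           error = function(e) NA_real_)
}

#' Bootstrap CI for an RDM correlation
#'
#' Resamples stimuli with replacement (within each stratum when
#' `stratified`), rebuilds both dissimilarity matrices with the same
#' stimulus multiset, removes undefined cells — the diagonal and any cell
#' pairing a stimulus with a duplicate of itself — and correlates the
#' remaining upper-triangle values at each iteration.
#'
#' @param a,b Matched [rdm] objects.
#' @param stratified Resample within strata (taken from `a`; both RDMs must
#'   carry identical strata).
#' @param n_iter Iterations (default 1000).
#' @param seed Integer seed.
#' @param method Correlation method, see [rdm_correlation()].
#' @return A [bootstrap_result]; `$point` is the non-bootstrap
#'   [rdm_correlation()], `$resample_log` the n_iter x n index draws.
#' @export
bootstrap_rdm_correlation <- function(a, b, stratified = FALSE,
                                      n_iter = 1000, seed = 1,
                                      method = "pearson") {
  am <- as.matrix(a); bm <- as.matrix(b)
  if (!all(dim(am) == dim(bm))) {
    stop("RDM size mismatch: ", nrow(am), " vs ", nrow(bm))
  }
  strata <- .check_strata(a, b, stratified)
  n <- nrow(am)
  point <- rdm_correlation(a, b, method = method)
  log_ <- matrix(0L, n_iter, n)
  reps <- .with_seed(seed, {
    vapply(seq_len(n_iter), function(i) {
      idx <- .resample_indices(n, strata)
      log_[i, ] <<- idx
      .resampled_correlation(am, bm, idx, method)
    }, numeric(1))
  })
  bootstrap_result(point, reps, n_iter, seed,
                   extra = list(resample_log = log_, stratified = stratified))
}

#' Bootstrap several model RDMs against one reference with shared draws
#'
#' Correlates each model RDM with the same reference RDM under a *common*
#' sequence of stimulus resamples, so the replicate columns are paired
#' across models — the alignment [paired_group_test()] requires.
#'
#' @param models Named list of [rdm] objects (one per model).
#' @param reference Reference [rdm].
#' @param stratified,n_iter,seed,method As in [bootstrap_rdm_correlation()].
#' @return List with `points` (named vector), `replicates` (n_iter x models
#'   matrix), `resample_log`, `n_iter`, `seed`.
#' @export
bootstrap_rdm_correlations <- function(models, reference, stratified = FALSE,
                                       n_iter = 1000, seed = 1,
                                       method = "pearson") {
  stopifnot(is.list(models), length(models) >= 1)
  if (is.null(names(models))) names(models) <- paste0("m", seq_along(models))
  ref <- as.matrix(reference)
  strata <- .check_strata(reference, NULL, stratified)
  n <- nrow(ref)
  mats <- lapply(models, as.matrix)
  points <- vapply(models, rdm_correlation, numeric(1), b = reference,
                   method = method)
  log_ <- matrix(0L, n_iter, n)
  reps <- .with_seed(seed, {
    t(vapply(seq_len(n_iter), function(i) {
      idx <- .resample_indices(n, strata)
      log_[i, ] <<- idx
      vapply(mats, .resampled_correlation, numeric(1), b = ref, idx = idx,
             method = method)
    }, numeric(length(models))))
  })
  reps <- matrix(reps, nrow = n_iter, ncol = length(models),
                 dimnames = list(NULL, names(models)))
  list(points = points, replicates = reps, resample_log = log_,
       n_iter = n_iter, seed = seed)
}

#' Bootstrapped paired-samples group test
#'
#' Compares two groups of models on paired bootstrap replicates: at each
#' iteration, performance is averaged across the models within each group
#' and the group difference is taken; the p-value is the fraction of
#' difference replicates below zero (one-tailed, floored at `1/n_iter`),
#' doubled and capped at 1 for the two-tailed version. Replicates must be
#' aligned on the same resampling draws (see
#' [bootstrap_rdm_correlations()]). Identical groups (all differences
#' exactly zero) return p = 1 by convention.
#'
#' @param replicates1,replicates2 Replicate matrices (iterations x models)
#'   or vectors, drawn on the same resamples.
#' @param tail `"one"` or `"two"`.
#' @return List with `p`, `tail`, `mean_difference`, `differences`.
#' @export
paired_group_test <- function(replicates1, replicates2,
                              tail = c("one", "two")) {
  tail <- match.arg(tail)
  r1 <- as.matrix(replicates1); r2 <- as.matrix(replicates2)
  if (nrow(r1) != nrow(r2)) {
    stop("unpaired replicates: ", nrow(r1), " vs ", nrow(r2), " iterations")
  }
  d <- rowMeans(r1) - rowMeans(r2)
  d <- d[!is.na(d)]
  n <- length(d)
  if (n == 0) stop("no defined difference replicates")
  if (all(d == 0)) {
    return(list(p = 1, tail = tail, mean_difference = 0, differences = d))
  }
  p_below <- max(mean(d < 0), 1 / n)
  p <- if (tail == "one") p_below else min(1, 2 * min(p_below,
                                                      max(mean(d > 0),
                                                          1 / n)))
  list(p = p, tail = tail, mean_difference = mean(d), differences = d)
}

#' Noise ceiling of a participant RDM stack
#'
#' Bounds on the RDM correlation any model could reach with the group
#' average, given inter-participant variability. Each participant's
#' upper-triangle vector is z-scored; the upper bound is the mean
#' correlation between each participant and the grand mean (including that
#' participant), the lower bound the mean correlation with the
#' leave-one-out mean.
#'
#' @param stack List of matched participant [rdm]s (>= 2 participants).
#' @return List with `lower` and `upper` (`lower <= upper`).
#' @export
noise_ceiling <- function(stack) {
  if (length(stack) < 2) stop("noise ceiling needs at least 2 participants")
  vecs <- lapply(stack, upper_tri)
  for (i in seq_along(vecs)) {
    if (stats::sd(vecs[[i]]) == 0) {
      stop("participant ", i, " has zero upper-triangle variance")
    }
  }
  z <- vapply(vecs, function(v) as.numeric(scale(v)),
              numeric(length(vecs[[1]])))
  grand <- rowMeans(z)
  upper <- mean(vapply(seq_len(ncol(z)),
                       function(i) stats::cor(z[, i], grand), numeric(1)))
  lower <- mean(vapply(seq_len(ncol(z)), function(i) {
    stats::cor(z[, i], rowMeans(z[, -i, drop = FALSE]))
  }, numeric(1)))
  list(lower = lower, upper = upper)
}
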