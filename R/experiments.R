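# Experiment drivers: naming consistency, physical-vs-perceived layer
# profiles, non-accidental-property triplet discrimination, and
# shape-vs-category comparison. Each driver returns a machine-readable
# result bundle (points, CIs, ceiling band, embeddings) sufficient to
# re-render its figure analogue without recomputation.

#' Assemble a naming dataset
#'
#' @param items Data frame with columns `item_id`, `name`; optional
#'   list-column `synonyms` (character vectors, may overlap across items).
#' @param human_responses Character matrix (participants x items) of
#'   responses, columns ordered as `items`.
#' @param model_responses Character vector of model responses, one per item,
#'   or a named list of such vectors for several models.
#' @param response_list Closed list of admissible responses (default: all
#'   names and synonyms in `items`).
#' @return A `naming_dataset`.
#' @export
naming_dataset <- function(items, human_responses, model_responses,
                           response_list = NULL) {
  stopifnot(all(c("item_id", "name") %in% names(items)))
  if (is.null(items$synonyms)) {
    items$synonyms <- replicate(nrow(items), character(0), simplify = FALSE)
  }
  if (!is.list(model_responses)) {
    model_responses <- list(model = model_responses)
  }
  if (is.null(response_list)) {
    response_list <- unique(c(items$name, unlist(items$synonyms)))
  }
  all_resp <- c(as.vector(human_responses), unlist(model_responses))
  bad <- setdiff(unique(all_resp), response_list)
  if (length(bad)) {
    stop("response(s) outside the closed response list: ",
         paste(bad, collapse = ", "))
  }
  structure(list(items = items, human_responses = human_responses,
                 model_responses = model_responses,
                 response_list = response_list),
            class = "naming_dataset")
}

# 1 if a response names the item or one of its synonyms
.score_responses <- function(responses, items) {
  vapply(seq_len(nrow(items)), function(i) {
    as.numeric(responses[i] %in% c(items$name[i], items$synonyms[[i]]))
  }, numeric(1))
}

#' Score a naming dataset
#'
#' Computes per-item and overall accuracy for each human participant and
#' each model, the consistency between every model's accuracy vector and
#' the mean-human accuracy vector (the matching-distance statistic of
#' [consistency()]), and a between-human consistency ceiling band: the
#' upper bound averages each participant's consistency with the group mean
#' including themselves, the lower bound with the leave-one-out mean.
#'
#' @param dataset A [naming_dataset()].
#' @return List with `human_item_accuracy` (matrix), `mean_human_accuracy`,
#'   `human_overall`, `model_item_accuracy`, `model_overall`,
#'   `model_human_consistency`, `model_model_consistency`, `ceiling`.
#' @export
score_naming <- function(dataset) {
  stopifnot(inherits(dataset, "naming_dataset"))
  items <- dataset$items
  hr <- dataset$human_responses
  n_part <- nrow(hr)
  human_acc <- t(vapply(seq_len(n_part),
                        function(p) .score_responses(hr[p, ], items),
                        numeric(nrow(items))))
  colnames(human_acc) <- items$item_id
  mean_human <- colMeans(human_acc)
  model_acc <- vapply(dataset$model_responses, .score_responses,
                      numeric(nrow(items)), items = items)
  model_acc <- t(model_acc)  # models x items
  rownames(model_acc) <- names(dataset$model_responses)
  mh <- apply(model_acc, 1, consistency, y = mean_human)
  mm <- if (nrow(model_acc) >= 2) {
    cmb <- utils::combn(nrow(model_acc), 2)
    stats::setNames(
      apply(cmb, 2, function(ij) consistency(model_acc[ij[1], ],
                                             model_acc[ij[2], ])),
      apply(cmb, 2, function(ij) paste(rownames(model_acc)[ij], collapse = "|")))
  } else NULL
  upper <- mean(vapply(seq_len(n_part),
                       function(p) consistency(human_acc[p, ], mean_human),
                       numeric(1)))
  lower <- if (n_part >= 2) {
    mean(vapply(seq_len(n_part), function(p) {
      consistency(human_acc[p, ], colMeans(human_acc[-p, , drop = FALSE]))
    }, numeric(1)))
  } else NA_real_
  list(human_item_accuracy = human_acc, mean_human_accuracy = mean_human,
       human_overall = rowMeans(human_acc),
       model_item_accuracy = model_acc,
       model_overall = rowMeans(model_acc),
       model_human_consistency = mh, model_model_consistency = mm,
       ceiling = list(lower = lower, upper = upper))
}

#' Logistic slope test of model-vs-human naming difficulty
#'
#' Regresses per-item model correctness on mean human accuracy with a
#' logistic model and tests the slope against zero (Wald z). A reliably
#' positive slope means the model tends to fail on the items humans find
#' hard. Under complete separation the Wald statistic degenerates; the
#' slope is then reported as infinite and the p-value falls back to a
#' likelihood-ratio test, which stays finite. A constant model vector gives
#' an undefined slope, flagged rather than raised.
#'
#' @param human_item_accuracy Per-item mean human accuracy in \[0, 1\].
#' @param model_item_correct Per-item binary model correctness.
#' @return List with `slope`, `z`, `p`, `degenerate`, `separation`.
#' @export
naming_slope_test <- function(human_item_accuracy, model_item_correct) {
  x <- as.numeric(human_item_accuracy)
  y <- as.numeric(model_item_correct)
  if (length(x) != length(y)) stop("item count mismatch")
  if (any(x < 0 | x > 1)) stop("human accuracies must lie in [0, 1]")
  if (length(unique(y)) < 2) {
    return(list(slope = NA_real_, z = NA_real_, p = NA_real_,
                degenerate = TRUE, separation = FALSE))
  }
  fit <- suppressWarnings(stats::glm(y ~ x, family = stats::binomial()))
  co <- summary(fit)$coefficients
  slope <- co["x", "Estimate"]
  se <- co["x", "Std. Error"]
  fitted_extreme <- any(fit$fitted.values < 1e-8 |
                          fit$fitted.values > 1 - 1e-8)
  separation <- fitted_extreme && (se > 1e3 || abs(slope) > 1e2)
  if (separation) {
    lrt <- stats::anova(stats::glm(y ~ 1, family = stats::binomial()), fit,
                        test = "Chisq")
    p <- lrt$`Pr(>Chi)`[2]
    return(list(slope = sign(slope) * Inf, z = NA_real_, p = p,
                degenerate = FALSE, separation = TRUE))
  }
  z <- slope / se
  list(slope = slope, z = z, p = 2 * stats::pnorm(-abs(z)),
       degenerate = FALSE, separation = FALSE)
}

# shared machinery for the two layer-profile drivers
.layer_profile <- function(layers, references, stratified, n_iter, seed,
                           metric) {
  stopifnot(is.list(layers), length(layers) >= 1)
  if (is.null(names(layers))) {
    names(layers) <- vapply(layers, function(x) attr(x, "layer_name"),
                            character(1))
  }
  ids <- stimulus_ids(references[[1]])
  rows <- list()
  for (l in seq_along(layers)) {
    fm <- layers[[l]]
    if (!identical(stimulus_ids(fm), ids)) {
      stop("layer '", names(layers)[l],
           "' does not cover the reference stimuli")
    }
    layer_rdm <- compute_rdm(fm, metric = metric)
    for (ref_name in names(references)) {
      ref <- references[[ref_name]]
      if (!identical(stimulus_ids(ref), ids)) {
        stop("reference RDMs carry mismatched stimuli")
      }
      strat_here <- stratified && !is.null(attr(ref, "strata"))
      if (stratified && is.null(attr(ref, "strata"))) {
        stop("stratified resampling requested but reference '", ref_name,
             "' carries no strata")
      }
      if (strat_here) attr(layer_rdm, "strata") <- attr(ref, "strata")
      bs <- bootstrap_rdm_correlation(layer_rdm, ref,
                                      stratified = strat_here,
                                      n_iter = n_iter,
                                      seed = as.integer(seed) + l)
      rows[[length(rows) + 1]] <- data.frame(
        layer = names(layers)[l], layer_index = l, reference = ref_name,
        correlation = bs$point, ci_low = bs$ci_low, ci_high = bs$ci_high,
        n_iter = n_iter, stringsAsFactors = FALSE)
    }
  }
  profile <- do.call(rbind, rows)
  class(profile) <- c("layer_profile", "data.frame")
  profile
}

#' Physical-form versus perceived-shape layer profile
#'
#' For each model layer, builds the layer RDM and correlates it with a
#' physical-form reference RDM and a perceived-shape reference RDM, with
#' bootstrap CIs. Across the depth of a representation that mirrors human
#' judgments, the perceived correlation rises while the physical one falls
#' at the top layers.
#'
#' @param layers List of [feature_matrix] objects, ordered bottom to top.
#' @param rdm_physical,rdm_perceived Reference [rdm]s on the same stimuli.
#' @param stratified Use stratified resampling (strata from each reference).
#' @param n_iter Bootstrap iterations per (layer, reference).
#' @param seed Integer seed.
#' @param metric Dissimilarity metric for the layer RDMs.
#' @return A `layer_profile` data frame: layer, layer_index, reference
#'   (`"physical"`/`"perceived"`), correlation, ci_low, ci_high.
#' @export
physical_vs_perceived <- function(layers, rdm_physical, rdm_perceived,
                                  stratified = FALSE, n_iter = 1000,
                                  seed = 1, metric = "correlation") {
  .layer_profile(layers,
                 list(physical = rdm_physical, perceived = rdm_perceived),
                 stratified, n_iter, seed, metric)
}

#' Shape versus category layer profile
#'
#' As [physical_vs_perceived()], but against perceived-shape and
#' semantic-category reference RDMs carrying their own strata (shape groups
#' and categories respectively); each reference is resampled within its own
#' strata. Optionally runs paired group tests between named groups of
#' models on the category reference.
#'
#' @param layers List of [feature_matrix] objects.
#' @param rdm_shape,rdm_category Reference [rdm]s with strata.
#' @param stratified Use each reference's strata when resampling (default
#'   `TRUE`).
#' @param model_groups Optional named list mapping group names to layer
#'   names, for paired group comparisons per reference.
#' @param n_iter,seed,metric As in [physical_vs_perceived()].
#' @return List with `profile` (a `layer_profile`) and, when `model_groups`
#'   is given, `group_tests` (data frame of pairwise one-tailed tests per
#'   reference).
#' @export
shape_vs_category <- function(layers, rdm_shape, rdm_category,
                              stratified = TRUE, model_groups = NULL,
                              n_iter = 1000, seed = 1,
                              metric = "correlation") {
  profile <- .layer_profile(layers,
                            list(shape = rdm_shape, category = rdm_category),
                            stratified, n_iter, seed, metric)
  out <- list(profile = profile)
  if (!is.null(model_groups)) {
    if (is.null(names(layers))) {
      names(layers) <- vapply(layers, function(x) attr(x, "layer_name"),
                              character(1))
    }
    refs <- list(shape = rdm_shape, category = rdm_category)
    tests <- list()
    for (ref_name in names(refs)) {
      ref <- refs[[ref_name]]
      strat_here <- stratified && !is.null(attr(ref, "strata"))
      model_rdms <- lapply(layers, function(fm) {
        r <- compute_rdm(fm, metric = metric)
        if (strat_here) attr(r, "strata") <- attr(ref, "strata")
        r
      })
      bs <- bootstrap_rdm_correlations(model_rdms, ref,
                                       stratified = strat_here,
                                       n_iter = n_iter, seed = seed)
      pairs <- utils::combn(names(model_groups), 2)
      for (j in seq_len(ncol(pairs))) {
        g1 <- model_groups[[pairs[1, j]]]; g2 <- model_groups[[pairs[2, j]]]
        tst <- paired_group_test(bs$replicates[, g1, drop = FALSE],
                                 bs$replicates[, g2, drop = FALSE],
                                 tail = "one")
        tests[[length(tests) + 1]] <- data.frame(
          reference = ref_name, group1 = pairs[1, j], group2 = pairs[2, j],
          mean_difference = tst$mean_difference, p = tst$p,
          tail = tst$tail, stringsAsFactors = FALSE)
      }
    }
    out$group_tests <- do.call(rbind, tests)
  }
  out
}

# pairwise dissimilarity between two feature rows under a pipeline metric
.pair_distance <- function(x, y, metric) {
  switch(metric,
    correlation = 1 - stats::cor(x, y),
    normalized_euclidean = sqrt(sum((x / sqrt(sum(x^2)) -
                                       y / sqrt(sum(y^2)))^2)),
    euclidean = sqrt(sum((x - y)^2)),
    stop("unknown metric: ", metric))
}

#' Non-accidental-property triplet evaluation
#'
#' For each (base, NAP-variant, metric-variant) triplet, a representation is
#' scored correct when its dissimilarity between base and NAP variant
#' *strictly* exceeds that between base and metric variant — the signature
#' of heightened sensitivity to non-accidental shape changes, against the
#' linear-metric ordering in which the NAP variant is the closer one.
#' Ties count as incorrect and are tallied separately. Chance level is 50%.
#'
#' @param triplets A `triplet_set` (see [generate_triplet_features()]) or a
#'   list of three stimuli lists/feature matrices `base`, `nap`, `metric`.
#' @param extractor Optional feature extractor applied to each member when
#'   triplet members are [image_stimulus] objects; `NULL` treats members as
#'   feature rows.
#' @param metric `"correlation"`, `"normalized_euclidean"` or
#'   `"euclidean"`.
#' @param n_iter,seed Bootstrap settings for the accuracy CI over triplets.
#' @return List with `accuracy`, `ci` ([bootstrap_result]), `outcomes`
#'   (per-triplet 0/1), `ties` (count), `d_nap`, `d_metric`,
#'   `chance = 0.5`.
#' @export
nap_evaluate <- function(triplets, extractor = NULL, metric = "correlation",
                         n_iter = 1000, seed = 1) {
  get_rows <- function(part) {
    x <- triplets[[part]]
    if (!is.null(extractor)) {
      x <- do.call(rbind, lapply(x, extractor))
    }
    as.matrix(x)
  }
  base <- get_rows("base"); nap <- get_rows("nap"); met <- get_rows("metric")
  n <- nrow(base)
  if (n < 1) stop("need at least one triplet")
  d_nap <- d_met <- numeric(n)
  for (i in seq_len(n)) {
    d_nap[i] <- .pair_distance(base[i, ], nap[i, ], metric)
    d_met[i] <- .pair_distance(base[i, ], met[i, ], metric)
  }
  outcomes <- as.numeric(d_nap > d_met)
  ties <- sum(d_nap == d_met)
  ci <- bootstrap_accuracy_ci(outcomes, n_iter = n_iter, seed = seed)
  list(accuracy = mean(outcomes), ci = ci, outcomes = outcomes,
       ties = ties, d_nap = d_nap, d_metric = d_met, chance = 0.5)
}

#' Plot a layer profile
#'
#' Correlation with each reference RDM across layers, with bootstrap CI
#' ribbons.
#'
#' @param profile A `layer_profile` from [physical_vs_perceived()] or
#'   [shape_vs_category()].
#' @return A ggplot object.
#' @export
plot_layer_profile <- function(profile) {
  ggplot2::ggplot(profile,
                  ggplot2::aes(x = layer_index, y = correlation,
                               colour = reference, fill = reference)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = ci_low, ymax = ci_high),
                         alpha = 0.2, colour = NA) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "layer", y = "RDM correlation",
                  colour = "reference", fill = "reference") +
    ggplot2::theme_minimal()
}
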