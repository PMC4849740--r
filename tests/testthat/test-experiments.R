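make_naming_fixture <- function(human_acc, model_acc) {
  items <- data.frame(item_id = paste0("i", seq_along(model_acc)),
                      name = paste0("name", seq_along(model_acc)),
                      stringsAsFactors = FALSE)
  items$synonyms <- lapply(seq_along(model_acc),
                           function(i) paste0("syn", i))
  to_resp <- function(acc) ifelse(acc == 1, items$name, "miss")
  human <- t(apply(human_acc, 1, to_resp))
  naming_dataset(items, human, list(model = to_resp(model_acc)),
                 response_list = c(items$name, unlist(items$synonyms),
                                   "miss"))
}

test_that("score_naming scores names and synonyms against the closed list", {
  items <- data.frame(item_id = c("i1", "i2"), name = c("dog", "cat"),
                      stringsAsFactors = FALSE)
  items$synonyms <- list(c("puppy", "hound"), character(0))
  human <- rbind(c("puppy", "cat"), c("dog", "dog"))
  ds <- naming_dataset(items, human, list(m = c("hound", "cat")),
                       response_list = c("dog", "cat", "puppy", "hound"))
  sc <- score_naming(ds)
  expect_equal(unname(sc$human_overall), c(1, 0.5))
  expect_equal(unname(sc$model_overall), 1)
  expect_error(naming_dataset(items, rbind(c("wolf", "cat")),
                              list(m = c("dog", "cat")),
                              response_list = c("dog", "cat")),
               "wolf")
})

test_that("model-vs-human naming consistency reproduces the half-agreement value", {
  perfect <- matrix(1, 4, 8)
  ds <- make_naming_fixture(perfect, rep(1, 8))
  sc <- score_naming(ds)
  expect_equal(unname(sc$model_human_consistency), 1)
  expect_equal(sc$ceiling$upper, 1)
  # humans split 1/0 over halves; model right where humans are, then flipped
  human <- matrix(rep(c(1, 1, 1, 1, 0, 0, 0, 0), each = 4), 4)
  agree <- score_naming(make_naming_fixture(human,
                                            c(1, 1, 1, 1, 0, 0, 0, 0)))
  expect_equal(unname(agree$model_human_consistency), 1)
  flipped <- score_naming(make_naming_fixture(human,
                                              c(0, 0, 1, 1, 1, 1, 0, 0)))
  expect_equal(unname(flipped$model_human_consistency), 0.5)
})

test_that("human-model consistency rises with panel size under shared difficulties", {
  p <- seq(0.3, 0.95, length.out = 24)
  by_panel <- sapply(c(2, 12), function(n_panel) {
    mean(sapply(1:50, function(r) {
      human <- simulate_naming(p, n_panel, seed = 500 + r)
      model <- simulate_naming(p, 1, seed = 900 + r)
      consistency(colMeans(human), model[1, ])
    }))
  })
  expect_gt(by_panel[2], by_panel[1])
})

test_that("the logistic slope test is calibrated under the null and detects planted signal", {
  zs <- sapply(1:200, function(s) {
    set.seed(s)
    human <- runif(60, 0.2, 1)
    model <- rbinom(60, 1, 0.6)  # independent of human difficulty
    naming_slope_test(human, model)$z
  })
  expect_gte(mean(abs(zs) < 1.96, na.rm = TRUE), 0.9)
  set.seed(7)
  human <- runif(80, 0, 1)
  model <- as.numeric(runif(80) < plogis(4 * (human - 0.5)))
  planted <- naming_slope_test(human, model)
  expect_gt(planted$z, 0)
  degen <- naming_slope_test(runif(10), rep(1, 10))
  expect_true(degen$degenerate)
  expect_true(is.na(degen$slope))
})

test_that("complete separation yields the infinite-slope fallback, not a crash", {
  human <- c(runif(20, 0, 0.4), runif(20, 0.6, 1))
  model <- rep(c(0, 1), each = 20)
  res <- naming_slope_test(human, model)
  expect_true(res$separation)
  expect_true(is.infinite(res$slope))
  expect_lt(res$p, 0.001)
})

test_that("layer profiles separate physical from perceived structure", {
  refs <- factorial_references()
  L <- simulate_layer_features(c(0, 1), refs$physical, refs$perceived,
                               n_features = 800, noise_sd = 0, seed = 21)
  prof <- physical_vs_perceived(L, refs$physical, refs$perceived,
                                n_iter = 200, seed = 22)
  top_perc <- prof[prof$layer_index == 2 & prof$reference == "perceived", ]
  top_phys <- prof[prof$layer_index == 2 & prof$reference == "physical", ]
  expect_gt(top_perc$correlation, 0.9)
  expect_gt(top_perc$ci_low, top_phys$correlation)  # CI excludes physical
  expect_error(physical_vs_perceived(L, refs$physical,
                                     random_rdm(5, 10)), "mismatch")
})

test_that("pixelwise features of the generated set track physical form over perceived class", {
  st <- generate_shape_set(shape_design(3, 3, seed = 1))
  refs <- factorial_references()
  ids <- names(st)
  phys <- rdm(unclass(refs$physical), stimulus_ids = ids,
              metric = "external")
  perc <- rdm(unclass(refs$perceived), stimulus_ids = ids,
              metric = "external")
  prof <- physical_vs_perceived(list(pix = model_features(st, "pixelwise")),
                                phys, perc, n_iter = 100, seed = 23)
  expect_gt(prof$correlation[prof$reference == "physical"],
            prof$correlation[prof$reference == "perceived"])
})

test_that("triplet evaluation scores the planted sets at the extremes", {
  ts <- generate_triplet_features(22, 1, 2, perceptual_gain = 5, seed = 24)
  linear <- nap_evaluate(ts, metric = "euclidean", n_iter = 100, seed = 25)
  expect_equal(linear$accuracy, 0)
  expect_equal(linear$ties, 0)
  amplified <- nap_evaluate(apply_perceptual_gain(ts), metric = "euclidean",
                            n_iter = 100, seed = 25)
  expect_equal(amplified$accuracy, 1)
  expect_equal(amplified$ci$ci_low, 1)
  # degenerate all-equal representations tie rather than crash
  flat <- list(base = matrix(1:4, 2), nap = matrix(1:4, 2),
               metric = matrix(1:4, 2))
  tied <- nap_evaluate(flat, metric = "euclidean", n_iter = 50)
  expect_equal(tied$accuracy, 0)
  expect_equal(tied$ties, 2)
})

test_that("triplet accuracy is invariant to a common rotation under normalized Euclidean", {
  ts <- generate_triplet_features(10, 1, 1.3, perceptual_gain = 3,
                                  n_features = 40, seed = 26)
  set.seed(27)
  Q <- qr.Q(qr(matrix(rnorm(1600), 40)))
  rot <- lapply(ts[c("base", "nap", "metric")], function(m) m %*% Q)
  before <- nap_evaluate(ts, metric = "normalized_euclidean", n_iter = 10)
  after <- nap_evaluate(rot, metric = "normalized_euclidean", n_iter = 10)
  expect_identical(before$outcomes, after$outcomes)
})

test_that("shape and category references of a balanced design are orthogonal", {
  grid <- expand.grid(shape = sprintf("sh%d", 1:9),
                      category = sprintf("cat%d", 1:6),
                      stringsAsFactors = FALSE)
  ids <- sprintf("o%02d", seq_len(nrow(grid)))
  r_shape <- label_rdm(stats::setNames(grid$shape, ids))
  r_cat <- label_rdm(stats::setNames(grid$category, ids))
  # closed form for disjoint same-shape / same-category pair sets:
  # cor = -sqrt(ab)/n / sqrt((1 - a/n)(1 - b/n)) with a, b the same-label
  # pair counts among the n stimulus pairs
  n_pairs <- choose(54, 2)
  a <- 6 * choose(9, 2)   # same-category pairs
  b <- 9 * choose(6, 2)   # same-shape pairs
  closed <- -sqrt(a * b) / n_pairs /
    sqrt((1 - a / n_pairs) * (1 - b / n_pairs))
  expect_equal(rdm_correlation(r_shape, r_cat), closed, tolerance = 1e-12)
  expect_lt(abs(rdm_correlation(r_shape, r_cat)), 0.15)
  # a layer built from category structure only prefers the category RDM
  L <- simulate_layer_features(1, r_shape, r_cat, n_features = 300,
                               noise_sd = 0, seed = 28)
  res <- shape_vs_category(L, r_shape, r_cat, n_iter = 100, seed = 29)
  cat_row <- res$profile[res$profile$reference == "category", ]
  shape_row <- res$profile[res$profile$reference == "shape", ]
  expect_gt(cat_row$ci_low, shape_row$ci_high)  # non-overlapping CIs
})

test_that("group comparisons run on paired replicates within the category driver", {
  grid <- expand.grid(shape = sprintf("sh%d", 1:4),
                      category = sprintf("cat%d", 1:4),
                      stringsAsFactors = FALSE)
  ids <- sprintf("o%02d", seq_len(nrow(grid)))
  r_shape <- label_rdm(stats::setNames(grid$shape, ids))
  r_cat <- label_rdm(stats::setNames(grid$category, ids))
  L <- simulate_layer_features(c(0.05, 0.95), r_shape, r_cat,
                               n_features = 300, noise_sd = 0, seed = 30)
  res <- shape_vs_category(L, r_shape, r_cat,
                           model_groups = list(high = "layer_2",
                                               low = "layer_1"),
                           n_iter = 200, seed = 31)
  gt <- res$group_tests
  cat_test <- gt[gt$reference == "category", ]
  expect_lt(cat_test$p, 0.05)          # high-mix group wins on category
  expect_gt(cat_test$mean_difference, 0)
})

test_that("the full synthetic pipeline recovers the rising perceived-shape profile", {
  refs <- factorial_references()
  L <- simulate_layer_features(seq(0, 1, length.out = 5), refs$physical,
                               refs$perceived, n_features = 600,
                               noise_sd = 0.1, seed = 32)
  prof <- physical_vs_perceived(L, refs$physical, refs$perceived,
                                n_iter = 50, seed = 33)
  perc <- prof[prof$reference == "perceived", ]
  phys <- prof[prof$reference == "physical", ]
  # top-minus-bottom signature of the crossover
  expect_gt(perc$correlation[5] - perc$correlation[1], 0)
  expect_lt(phys$correlation[5] - phys$correlation[1], 0)
})
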