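test_that("preprocess_image resamples to the target side and rescales to [0, 1]", {
  set.seed(1)
  big <- matrix(runif(512 * 512), 512)
  out <- preprocess_image(big, target_side = 256)
  expect_equal(dim(out$pixels), c(256, 256))
  expect_equal(range(out$pixels), c(0, 1))
  # an already-standard image passes through unchanged
  m <- matrix(seq(0, 1, length.out = 256 * 256), 256)
  expect_equal(preprocess_image(m, 256)$pixels, m, tolerance = 1e-12)
  # 8-bit-style input is mapped onto the full unit range
  bytes <- matrix(sample(0:255, 64 * 64, replace = TRUE), 64)
  bytes[1] <- 0; bytes[2] <- 255
  out8 <- preprocess_image(bytes / 255, target_side = 64)
  expect_equal(min(out8$pixels), 0)
  expect_equal(max(out8$pixels), 1)
})

test_that("preprocess_image converts color with Rec.601 weights and flags flat images", {
  rgb <- array(0, c(64, 64, 3))
  rgb[, , 1] <- 1  # pure red
  rgb[1, 1, ] <- 1 # one white pixel to give dynamic range
  out <- preprocess_image(rgb, 64)
  expect_equal(out$variant, "grayscale")
  # red luminance 0.299 maps to 0 ... white to 1 after min-max rescale
  expect_equal(out$pixels[1, 1], 1)
  expect_equal(out$pixels[2, 2], 0)
  expect_warning(flat <- preprocess_image(matrix(0.4, 32, 32), 32),
                 "dynamic range")
  expect_true(attr(flat, "zero_dynamic_range"))
  expect_true(all(flat$pixels == 0.4))
})

test_that("silhouettes fill cavities: an annulus becomes a disk", {
  side <- 128
  sil <- make_silhouette(annulus_image(side), 0.5)
  disk <- radial_grid(side) < 0.8
  expect_identical(sil$pixels < 0.5, disk)
  expect_equal(sil$variant, "silhouette")
  expect_true(all(sil$pixels %in% c(0, 1)))
})

test_that("silhouetting is idempotent on solid shapes and only adds pixels", {
  solid <- matrix(1, 64, 64); solid[20:40, 15:50] <- 0
  st <- image_stimulus(solid)
  once <- make_silhouette(st)
  expect_identical(once$pixels, solid)
  expect_identical(make_silhouette(once)$pixels, once$pixels)
  # hole-filling can only grow the sub-threshold set of a connected shape:
  # overlapping discs all containing the center form a single component
  set.seed(2)
  for (rep in 1:5) {
    m <- matrix(1, 64, 64)
    ctr <- matrix(runif(6, 0.42, 0.58) * 64, 3)
    for (b in 1:3) {
      r2 <- outer((seq_len(64) - ctr[b, 1])^2, (seq_len(64) - ctr[b, 2])^2,
                  "+")
      m[r2 < runif(1, 14, 20)^2] <- 0
    }
    out <- make_silhouette(image_stimulus(m))
    expect_gte(sum(out$pixels < 0.5), sum(m < 0.5))
  }
  expect_error(make_silhouette(image_stimulus(matrix(1, 32, 32))),
               "threshold")
})

test_that("pixelwise features flatten the image row-major and preserve identity", {
  m <- matrix(seq(0, 1, length.out = 16), 4, byrow = TRUE)
  st <- image_stimulus(m)
  expect_identical(pixelwise_features(st), as.vector(t(m)))
  st256 <- image_stimulus(matrix(runif(256^2), 256))
  expect_length(pixelwise_features(st256), 65536)
  expect_identical(pixelwise_features(st256), pixelwise_features(st256))
  # correlation distance between an image and its negative is 2
  a <- pixelwise_features(st)
  fm <- feature_matrix(rbind(a, 1 - a))
  expect_equal(unclass(compute_rdm(fm))[1, 2], 2, tolerance = 1e-12)
})

test_that("the Gabor jet has the documented geometry and is silent on constant images", {
  st <- image_stimulus(matrix(0.5, 256, 256))
  jet <- gaborjet_features(st)
  expect_length(jet, 5 * 8 * 10 * 10)
  expect_lt(max(abs(jet)), 1e-10)
  expect_error(gaborjet_features(image_stimulus(matrix(0.5, 8, 8)),
                                 grid = 10), "grid")
})

test_that("Gabor-jet channel energy peaks at the matching grating orientation and frequency", {
  freqs <- (pi / 2) / 2^(0:4)
  for (case in list(c(o = 0, f = 2), c(o = 3, f = 3), c(o = 6, f = 4))) {
    phi <- case[["o"]] * pi / 8
    st <- grating_image(256, phi = phi, k = freqs[case[["f"]]])
    jet <- matrix(gaborjet_features(st), ncol = 40, byrow = TRUE)
    energy <- colSums(jet)   # per (frequency, orientation) channel
    best <- which.max(energy) - 1
    expect_equal(best %/% 8 + 1, case[["f"]], ignore_attr = TRUE)
    expect_equal(best %% 8, case[["o"]], ignore_attr = TRUE)
  }
})

test_that("HOG descriptors have the counted length, zero response to flat input, unit range", {
  st <- image_stimulus(matrix(0.5, 256, 256))
  h <- hog_features(st)
  expect_length(h, (256 / 8 - 3 + 1)^2 * 3^2 * 9)
  expect_true(all(h == 0))
  textured <- image_stimulus(matrix(runif(128^2), 128))
  ht <- hog_features(textured)
  expect_true(all(ht >= 0 & ht <= 1))
  expect_error(hog_features(image_stimulus(matrix(0.5, 100, 100))),
               "divisible")
})

test_that("rotating a grating by 90 degrees moves the dominant HOG orientation accordingly", {
  # gradient direction of a phi-grating is phi itself (mod pi)
  st_v <- grating_image(128, phi = pi / 2, k = pi / 4)  # gradients at 90 deg
  st_h <- grating_image(128, phi = 0, k = pi / 4)       # gradients at 0 deg
  mass <- function(st) {
    h <- hog_features(st)
    colSums(matrix(h, ncol = 9, byrow = TRUE))
  }
  expect_equal(which.max(mass(st_v)), 5)  # bin centered on 90 degrees
  expect_true(which.max(mass(st_h)) %in% c(1, 9))  # 0 deg wraps both ends
})

test_that("activation containers round-trip, realign and report missing layers", {
  set.seed(3)
  layers <- list(
    conv1 = feature_matrix(matrix(rnorm(20), 4), layer_name = "conv1",
                           stimulus_ids = c("a", "b", "c", "d")),
    fc7 = feature_matrix(matrix(rnorm(12), 4), layer_name = "fc7",
                         stimulus_ids = c("a", "b", "c", "d")))
  path <- withr::local_tempdir()
  write_activation_container(layers, path)
  back <- load_activation_matrix(path, "conv1")
  expect_equal(unclass(back), unclass(layers$conv1), tolerance = 1e-12,
               ignore_attr = TRUE)
  perm <- load_activation_matrix(path, "fc7",
                                 stimulus_ids = c("d", "a", "c", "b"))
  expect_equal(unclass(perm), unclass(layers$fc7)[c(4, 1, 3, 2), ],
               tolerance = 1e-12, ignore_attr = TRUE)
  expect_error(load_activation_matrix(path, "fc8"), "fc8")
  expect_error(load_activation_matrix(path, "conv1",
                                      stimulus_ids = c("a", "zz")), "zz")
})

test_that("model_features stacks extractor rows with stimulus labels", {
  st <- generate_shape_set(shape_design(2, 2, image_side = 64, seed = 1))
  fm <- model_features(st, "hog")
  expect_s3_class(fm, "feature_matrix")
  expect_equal(nrow(fm), 4)
  expect_identical(stimulus_ids(fm), names(st))
  expect_identical(unclass(fm), unclass(model_features(st, "hog")))
})
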