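# Fixtures built in code: small images, toy RDMs and reference designs.

# centered radial coordinate grid in [-1, 1]
radial_grid <- function(side) {
  ax <- (seq_len(side) - (side + 1) / 2) / (side / 2)
  sqrt(outer(ax^2, ax^2, "+"))
}

# black annulus (or disk when r_in = 0) on white background
annulus_image <- function(side = 128, r_in = 0.4, r_out = 0.8) {
  r <- radial_grid(side)
  m <- matrix(1, side, side)
  m[r < r_out & r >= r_in] <- 0
  image_stimulus(m)
}

# sinusoidal grating: orientation phi (radians), spatial frequency k
# (radians per pixel)
grating_image <- function(side = 256, phi = 0, k = pi / 8) {
  xm <- matrix(seq_len(side), side, side, byrow = TRUE)
  ym <- matrix(seq_len(side), side, side)
  image_stimulus(0.5 + 0.5 * cos(k * (cos(phi) * xm + sin(phi) * ym)))
}

# RDM of a random Gaussian feature matrix
random_rdm <- function(n = 9, p = 30, seed = 1, strata = NULL) {
  set.seed(seed)
  compute_rdm(matrix(rnorm(n * p), n,
                     dimnames = list(paste0("s", seq_len(n)), NULL)),
              strata = strata)
}

# the 3 x 3 factorial references used across pipeline tests: "physical"
# follows the envelope labels, "perceived" the class labels
factorial_references <- function() {
  ids <- paste0("s", 1:9)
  list(physical = label_rdm(stats::setNames(as.character(rep(1:3, 3)), ids)),
       perceived = label_rdm(stats::setNames(rep(c("a", "b", "c"),
                                                 each = 3), ids)))
}

# independent brute-force evaluation of the displayed Pearson formula
pearson_by_hand <- function(x, y) {
  sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
}
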