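# Small in-code fixtures shared across test files. Everything is generated
# at test time; nothing is read from disk.

# A small standardized, split, labeled dataset for fast training tests.
tiny_dataset <- function(n = 24, len = c(32, 48), seed = 7,
                         signal_strength = 1.5) {
  ds <- generate_emotion_dataset(n, length_range = len,
                                 signal_strength = signal_strength,
                                 seed = seed, standardize = FALSE)
  ds <- split_dataset(ds, 0.8, seed = seed)
  standardize_dataset(ds)
}

# Backbone parameters with small dimensions (internal initializers), for
# cheap kernel-level checks.
small_params <- function(d = 6, h = 5, seed = 1, with_head = FALSE) {
  withr_seed <- function(code) sslser:::with_seed(seed, code)
  k <- 1 / sqrt(h)
  withr_seed({
    p <- list(
      W1 = matrix(runif(3 * h * d, -k, k), 3 * h, d),
      U1 = matrix(runif(3 * h * h, -k, k), 3 * h, h),
      b1i = runif(3 * h, -k, k), b1h = runif(3 * h, -k, k),
      W2 = matrix(runif(3 * h * h, -k, k), 3 * h, h),
      U2 = matrix(runif(3 * h * h, -k, k), 3 * h, h),
      b2i = runif(3 * h, -k, k), b2h = runif(3 * h, -k, k),
      Wd = matrix(runif(d * h, -k, k), d, h),
      bd = runif(d, -k, k)
    )
    if (with_head) {
      p$Wh <- matrix(runif(6 * d, -0.3, 0.3), 6, d)
      p$bh <- runif(6, -0.3, 0.3)
    }
    p
  })
}

# Random score matrices on the intensity scale (with excursions outside
# [0, 3] for the clamping paths).
random_scores <- function(n, seed) {
  sslser:::with_seed(seed, {
    list(
      pred = matrix(runif(n * 6, -0.5, 3.5), n, 6),
      true = matrix(runif(n * 6, 0, 3), n, 6)
    )
  })
}
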