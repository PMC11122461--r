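# Independent oracles and shared fixtures.

# Closed-form sRGB (D65) -> XYZ -> CIE L*a*b*, written independently of the
# package implementation (scalar, loop-based, textbook constants).
oracle_rgb_to_lab <- function(rgb) {
  out <- matrix(0, nrow(rgb), 3)
  for (i in seq_len(nrow(rgb))) {
    chan <- numeric(3)
    for (j in 1:3) {
      v <- rgb[i, j] / 255
      chan[j] <- if (v <= 0.04045) v / 12.92 else ((v + 0.055) / 1.055)^2.4
    }
    x <- 0.4124564 * chan[1] + 0.3575761 * chan[2] + 0.1804375 * chan[3]
    y <- 0.2126729 * chan[1] + 0.7151522 * chan[2] + 0.0721750 * chan[3]
    z <- 0.0193339 * chan[1] + 0.1191920 * chan[2] + 0.9503041 * chan[3]
    xr <- x / 0.95047; yr <- y / 1.0; zr <- z / 1.08883
    f <- function(t) {
      if (t > (6 / 29)^3) t^(1 / 3) else t / (3 * (6 / 29)^2) + 4 / 29
    }
    out[i, ] <- c(116 * f(yr) - 16,
                  500 * (f(xr) - f(yr)),
                  200 * (f(yr) - f(zr)))
  }
  out
}

# Toy scale with simple arithmetic anchors around the spec'd example pair
# C_5 = (100,100,100), C_6 = (140,120,80); endpoints keep light -> dark.
toy_scale <- function() {
  anchors <- rbind(
    c(250, 250, 250), c(220, 220, 220), c(190, 190, 190), c(160, 160, 160),
    c(100, 100, 100), c(140, 120, 80), c(90, 80, 70), c(70, 60, 50),
    c(50, 40, 30), c(30, 20, 10)
  )
  monk_scale(anchors)
}

# Loop-based metric oracles (naive reimplementations used as references).
oracle_accuracy_at <- function(d, thr) {
  hits <- 0
  for (x in d) if (x <= thr) hits <- hits + 1
  100 * hits / length(d)
}

oracle_lab_errors <- function(est, tgt, scale) {
  d <- numeric(length(est))
  for (i in seq_along(est)) {
    a <- unlist(index_to_lab(scale, est[i])[, c("l", "a", "b")])
    b <- unlist(index_to_lab(scale, tgt[i])[, c("l", "a", "b")])
    d[i] <- sqrt(sum((a - b)^2))
  }
  mu <- sum(d) / length(d)
  sig <- sqrt(sum((d - mu)^2) / length(d))
  list(d = d, mu = mu, sigma = sig)
}

# A single-identity fixture with deterministic geometry.
fixture_identity <- function(tone = 5, seed = 99L) {
  ids <- sample_identities(1, seed = seed)
  ids$true_tone <- tone
  ids
}

neutral_condition <- function(exposure = 1, gains = c(1, 1, 1)) {
  tibble::tibble(light_type = "led_warm", intensity_level = 2L,
                 gain_r = gains[1], gain_g = gains[2], gain_b = gains[3],
                 exposure = exposure)
}

# Shared scaled-down experiment configurations.
recovery_config <- function(seed) {
  experiment_config(
    seed = seed,
    simulator = list(n_identities = 60L, rotations = "front", size = 64L,
                     noise_sigma = 2),
    input = list(colour_mode = "LAB", side = 64L),
    model = list(profile = "tiny"),
    train = list(learning_rate = 1e-3, epochs = 15L),
    ablation = list(augment = FALSE)
  )
}

ablation_config <- function(seed, complexion_sigma = 0, epochs = 15L, ...) {
  experiment_config(
    seed = seed,
    simulator = list(n_identities = 40L, rotations = "front", size = 32L,
                     noise_sigma = 2, complexion_sigma = complexion_sigma),
    input = list(colour_mode = "LAB", side = 32L),
    model = list(profile = "tiny"),
    train = list(learning_rate = 1e-3, epochs = epochs),
    ablation = list(augment = FALSE, ...)
  )
}

acc05 <- function(experiment) glance(experiment$report)$accuracy_0.5

# Run one experiment per seed until a majority of `pass` outcomes is
# decided either way; returns the pass verdict.
majority_verdict <- function(seeds, pass_fn) {
  passes <- 0; fails <- 0
  need <- ceiling((length(seeds) + 1) / 2)
  for (s in seeds) {
    if (isTRUE(pass_fn(s))) passes <- passes + 1 else fails <- fails + 1
    if (passes >= need || fails >= need) break
  }
  passes > fails
}
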