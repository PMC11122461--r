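#' The fifteen studio lighting conditions
#'
#' Five light types (warm/cool fluorescent, warm/cool LED, warm halogen),
#' each at three intensity levels, give the 15 capture conditions. The
#' illuminant is modelled diagonally (von Kries): a per-channel RGB gain
#' encodes the colour cast, and the intensity level sets a scalar exposure.
#' Warm types have a red-heavy gain, cool types a blue-heavy gain.
#'
#' @param intensity_exposures Exposure multipliers for intensity levels
#'   1..3. Defaults to `c(0.7, 1.0, 1.3)`.
#' @return A tibble with one row per condition: `light_type`,
#'   `intensity_level`, `gain_r`, `gain_g`, `gain_b`, `exposure`.
#' @export
lighting_conditions <- function(intensity_exposures = c(0.7, 1.0, 1.3)) {
  stopifnot(length(intensity_exposures) == 3, all(intensity_exposures > 0))
  presets <- tibble(
    light_type = c("fluorescent_warm", "fluorescent_cool",
                   "led_warm", "led_cool", "halogen_warm"),
    gain_r = c(1.15, 0.92, 1.10, 0.90, 1.25),
    gain_g = c(1.00, 1.00, 1.00, 1.00, 1.00),
    gain_b = c(0.85, 1.12, 0.90, 1.15, 0.75)
  )
  out <- tidyr::crossing(presets, intensity_level = 1:3)
  out$exposure <- intensity_exposures[out$intensity_level]
  out[, c("light_type", "intensity_level",
          "gain_r", "gain_g", "gain_b", "exposure")]
}

#' Head rotations captured per condition
#' @return Character vector of the five rotation labels.
#' @export
head_rotations <- function() c("front", "left", "right", "up", "down")

# Deterministic 31-bit string hash for deriving per-image RNG substreams.
hash_string <- function(s) {
  h <- 0
  for (k in utf8ToInt(s)) h <- (h * 131 + k) %% 2147483647
  as.integer(h)
}

derive_seed <- function(base, ...) {
  hash_string(paste(c(format(base), ...), collapse = "|"))
}

#' Sample synthetic identities with continuous Monk tone labels
#'
#' Draws `n` identities whose true tone follows a configurable distribution
#' over \[1, 10\]. The default emulates a recruitment pool in which the
#' extremes of the pigmentation spectrum are under-represented: a scaled
#' symmetric Beta, peaked mid-scale with thin tails at tones 1 and 10.
#' Face geometry (ellipse centre and axes, as fractions of the frame) is
#' jittered per identity. Each identity carries its own RNG seed, derived
#' by stable hashing from the master seed, so adding identities never
#' perturbs earlier ones.
#'
#' @param n Number of identities (>= 1).
#' @param seed Master integer seed.
#' @param tone_sampler Function `(n) -> tones in [1, 10]`; the default is
#'   `1 + 9 * rbeta(n, 2.2, 2.2)`.
#' @param complexion_sigma Standard deviation (tone units) of the
#'   per-identity gap between the assigned tone label and the rendered
#'   complexion, emulating inaccuracies in human tone assignment; default
#'   0 (labels exact).
#' @return A tibble: `identity_id`, `true_tone`, `complexion_delta`,
#'   `centre_x`, `centre_y`, `axis_x`, `axis_y` (fractions of frame
#'   side), `id_seed`.
#' @export
sample_identities <- function(n, seed = 1L, tone_sampler = NULL,
                              complexion_sigma = 0) {
  if (!is.numeric(n) || length(n) != 1 || n < 1) {
    abort("n must be a count >= 1")
  }
  n <- as.integer(n)
  tone_sampler <- tone_sampler %||% function(n) 1 + 9 * rbeta(n, 2.2, 2.2)
  withr::with_seed(as.integer(seed), {
    tones <- clamp(tone_sampler(n), 1, 10)
    tibble(
      identity_id = sprintf("id%04d", seq_len(n)),
      true_tone = tones,
      complexion_delta = if (complexion_sigma > 0) {
        rnorm(n, 0, complexion_sigma)
      } else {
        numeric(n)
      },
      centre_x = 0.5 + runif(n, -0.03, 0.03),
      centre_y = 0.5 + runif(n, -0.03, 0.03),
      axis_x = runif(n, 0.26, 0.34),
      axis_y = runif(n, 0.32, 0.40),
      id_seed = vapply(seq_len(n), function(i) {
        derive_seed(seed, "identity", i)
      }, integer(1))
    )
  })
}

# Rotation-adjusted ellipse geometry, in pixels for a size x size frame.
rotated_geometry <- function(identity, rotation, size) {
  cx <- identity$centre_x
  cy <- identity$centre_y
  ax <- identity$axis_x
  ay <- identity$axis_y
  switch(rotation,
    front = NULL,
    left  = { cx <- cx - 0.06; ax <- ax * 0.85 },
    right = { cx <- cx + 0.06; ax <- ax * 0.85 },
    up    = { cy <- cy - 0.06; ay <- ay * 0.90 },
    down  = { cy <- cy + 0.06; ay <- ay * 0.90 },
    abort(paste0("unknown rotation '", rotation, "'"))
  )
  list(cx = cx * size, cy = cy * size, ax = ax * size, ay = ay * size)
}

# Normalised elliptical radius field for a frame: r = 1 on ellipse boundary.
ellipse_radius <- function(geom, size) {
  x <- matrix(rep(seq_len(size) - 0.5, each = size), nrow = size)  # column
  y <- matrix(rep(seq_len(size) - 0.5, times = size), nrow = size) # row
  sqrt(((x - geom$cx) / geom$ax)^2 + ((y - geom$cy) / geom$ay)^2)
}

#' Ground-truth face masks for a rendered identity
#'
#' @param identity One row of [sample_identities()].
#' @param rotation One of [head_rotations()].
#' @param size Frame side in pixels.
#' @return A list with logical `size x size` matrices `face` (the full
#'   ellipse) and `core` (the inner, un-shaded region whose mean colour
#'   equals the interpolated tone colour), plus the bounding `box`
#'   (0-based, half-open `c(x0, y0, x1, y1)`).
#' @export
face_mask <- function(identity, rotation = "front", size = 128L) {
  geom <- rotated_geometry(identity, rotation, size)
  r <- ellipse_radius(geom, size)
  box <- c(
    floor(max(geom$cx - geom$ax, 0)), floor(max(geom$cy - geom$ay, 0)),
    ceiling(min(geom$cx + geom$ax, size)), ceiling(min(geom$cy + geom$ay, size))
  )
  list(face = r <= 1, core = r <= 0.6, box = box)
}

studio_core_radius <- 0.6  # shading and facial features start outside this

#' Render one synthetic studio image
#'
#' The face is a shaded ellipse whose base colour is the Monk interpolation
#' of the identity's rendered complexion (its true tone plus any
#' per-identity `complexion_delta`, emulating label-assignment error). The inner core (normalised radius <= 0.6)
#' is un-shaded pure base colour; outside it the shading falls off linearly
#' to 75% at the rim, and simple facial features (eyes, mouth) darken small
#' patches. Each pixel is then passed through the diagonal illuminant
#' model, `clip(exposure * gain * colour + noise)`, the grey backdrop
#' included, so the whole frame carries the light's colour cast. Rendering
#' is deterministic given (identity seed, condition, rotation).
#'
#' @param identity One row of [sample_identities()].
#' @param condition One row of [lighting_conditions()].
#' @param rotation One of [head_rotations()].
#' @param size Frame side in pixels (default 128).
#' @param noise_sigma Gaussian pixel noise standard deviation (8-bit units).
#' @param features Draw facial features (default `TRUE`).
#' @param chart Draw a small colour-chart patch block in the corner.
#' @param scale The [monk_scale()] used for the base colour.
#' @return An integer array `size x size x 3` with values in 0..255.
#' @export
render_image <- function(identity, condition, rotation = "front",
                         size = 128L, noise_sigma = 2,
                         features = TRUE, chart = FALSE,
                         scale = monk_scale()) {
  size <- as.integer(size)
  geom <- rotated_geometry(identity, rotation, size)
  if (geom$cx - geom$ax < 0 || geom$cx + geom$ax > size ||
      geom$cy - geom$ay < 0 || geom$cy + geom$ay > size) {
    abort("face geometry does not fit inside the frame")
  }
  r <- ellipse_radius(geom, size)
  face <- r <= 1
  shade <- matrix(1, size, size)
  rim <- face & r > studio_core_radius
  shade[rim] <- 1 - 0.25 * (r[rim] - studio_core_radius) /
    (1 - studio_core_radius)

  rendered_tone <- clamp(identity$true_tone +
                           rec_field(identity, "complexion_delta", 0), 1, 10)
  base <- interpolate_rgb_matrix(scale, rendered_tone)[1, ]
  backdrop <- c(120, 120, 120)
  img <- array(0, c(size, size, 3))
  for (c_i in 1:3) {
    ch <- matrix(backdrop[c_i], size, size)
    ch[face] <- base[c_i] * shade[face]
    img[, , c_i] <- ch
  }

  if (isTRUE(features)) {
    feat <- feature_mask(geom, size)
    for (c_i in 1:3) {
      ch <- img[, , c_i]
      ch[feat$eyes] <- base[c_i] * 0.35
      ch[feat$mouth] <- base[c_i] * 0.60
      img[, , c_i] <- ch
    }
  }
  if (isTRUE(chart)) {
    img <- draw_chart(img, size)
  }

  gains <- c(condition$gain_r, condition$gain_g, condition$gain_b)
  for (c_i in 1:3) {
    img[, , c_i] <- condition$exposure * gains[c_i] * img[, , c_i]
  }
  if (noise_sigma > 0) {
    img_seed <- derive_seed(identity$id_seed, condition$light_type,
                            condition$intensity_level, rotation)
    noise <- withr::with_seed(img_seed, rnorm(length(img), 0, noise_sigma))
    img <- img + noise
  }
  storage.mode(img) <- "double"
  array(as.integer(round(clamp(img, 0, 255))), dim(img))
}

# Eyes and mouth sit in the shaded annulus (outside the clean core).
feature_mask <- function(geom, size) {
  x <- matrix(rep(seq_len(size) - 0.5, each = size), nrow = size)
  y <- matrix(rep(seq_len(size) - 0.5, times = size), nrow = size)
  eye_r <- 0.10
  eye1 <- ((x - (geom$cx - 0.42 * geom$ax)) / (eye_r * geom$ax))^2 +
    ((y - (geom$cy - 0.62 * geom$ay)) / (eye_r * geom$ay))^2 <= 1
  eye2 <- ((x - (geom$cx + 0.42 * geom$ax)) / (eye_r * geom$ax))^2 +
    ((y - (geom$cy - 0.62 * geom$ay)) / (eye_r * geom$ay))^2 <= 1
  mouth <- ((x - geom$cx) / (0.28 * geom$ax))^2 +
    ((y - (geom$cy + 0.74 * geom$ay)) / (0.08 * geom$ay))^2 <= 1
  list(eyes = eye1 | eye2, mouth = mouth)
}

draw_chart <- function(img, size) {
  patch <- max(2L, size %/% 16)
  cols <- rbind(c(255, 0, 0), c(0, 255, 0), c(0, 0, 255),
                c(255, 255, 255), c(0, 0, 0), c(128, 128, 128))
  for (p in seq_len(nrow(cols))) {
    rows <- 1:patch
    colsel <- ((p - 1) * patch + 1):(p * patch)
    if (max(colsel) > size) break
    for (c_i in 1:3) img[rows, colsel, c_i] <- cols[p, c_i]
  }
  img
}

#' Build a labelled synthetic capture dataset
#'
#' Emulates the full capture protocol: every identity is imaged under every
#' lighting condition and every head rotation, so the record count is
#' `n_identities * nrow(conditions) * length(rotations)` (285 x 15 x 5 =
#' 21,375 at the default study scale). Returns the manifest as a tibble;
#' when `outdir` is given, PNG images and a `manifest.csv` are written.
#'
#' @param n_identities Number of identities (default 285).
#' @param conditions Tibble of lighting conditions
#'   (default [lighting_conditions()]).
#' @param rotations Character vector of rotations
#'   (default [head_rotations()]).
#' @param seed Master seed governing identities and pixel noise.
#' @param size Image side in pixels (default 128).
#' @param noise_sigma Gaussian pixel noise sd (default 2).
#' @param complexion_sigma Passed to [sample_identities()].
#' @param outdir Output directory for PNGs + manifest CSV, or `NULL` to
#'   build the manifest only (images can be re-rendered on the fly from
#'   manifest columns).
#' @param tone_sampler Passed to [sample_identities()].
#' @return A `capture_manifest` tibble: the canonical columns
#'   `image_path`, `identity_id`, `true_tone`, `light_type`,
#'   `intensity_level`, `rotation`, `split`, plus the rendering columns
#'   needed to regenerate each image (geometry, gains, exposure, seeds).
#' @export
build_dataset <- function(n_identities = 285, conditions = lighting_conditions(),
                          rotations = head_rotations(), seed = 1L,
                          size = 128L, noise_sigma = 2,
                          complexion_sigma = 0, outdir = NULL,
                          tone_sampler = NULL) {
  if (nrow(conditions) < 1 || length(rotations) < 1) {
    abort("conditions and rotations must be non-empty")
  }
  ids <- sample_identities(n_identities, seed = seed,
                           tone_sampler = tone_sampler,
                           complexion_sigma = complexion_sigma)
  records <- tidyr::crossing(
    ids,
    tidyr::crossing(conditions, rotation = rotations)
  )
  records <- arrange(records, .data$identity_id, .data$light_type,
                     .data$intensity_level, .data$rotation)
  records <- mutate(records,
    image_path = sprintf("%s_%s_i%d_%s.png", .data$identity_id,
                         .data$light_type, .data$intensity_level,
                         .data$rotation),
    split = "unassigned",
    size = as.integer(size),
    noise_sigma = noise_sigma
  )
  canonical <- c("image_path", "identity_id", "true_tone", "light_type",
                 "intensity_level", "rotation", "split")
  records <- records[, c(canonical, setdiff(names(records), canonical))]
  if (!is.null(outdir)) {
    if (!dir.exists(outdir)) {
      ok <- dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
      if (!ok) abort(paste0("cannot create output directory ", outdir))
    }
    for (i in seq_len(nrow(records))) {
      img <- render_record(records[i, ])
      png::writePNG(img / 255, file.path(outdir, records$image_path[i]))
    }
    write_manifest(records, file.path(outdir, "manifest.csv"))
  }
  structure(records, class = c("capture_manifest", class(records)))
}

#' Re-render the image for one manifest record
#'
#' Uses the rendering columns carried in the manifest so images never need
#' to be stored to be reproducible.
#'
#' @param record One manifest row.
#' @param scale The [monk_scale()] used for base colours.
#' @return An integer `size x size x 3` array.
#' @export
render_record <- function(record, scale = monk_scale()) {
  render_image(
    identity = record,
    condition = record,
    rotation = record$rotation,
    size = rec_field(record, "size", 128L),
    noise_sigma = rec_field(record, "noise_sigma", 2),
    scale = scale
  )
}

# tibble column access without unknown-column warnings
rec_field <- function(rec, nm, default) {
  if (nm %in% names(rec)) rec[[nm]] else default
}
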