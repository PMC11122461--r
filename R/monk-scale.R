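#' The Monk Skin Tone Scale colour model
#'
#' The Monk Skin Tone (MST) Scale is a 10-point scale of anchor colours
#' spanning light (index 1) to dark (index 10) skin tones. A continuous
#' tone index in \[1, 10\] maps to an sRGB colour by linear interpolation
#' between the two adjacent anchors.
#'
#' The packaged default anchors are the publicly documented MST sRGB values
#' (hex `#f6ede4` through `#292420`). Users may supply their own anchor
#' table, e.g. loaded with [read_monk_anchors()].
#'
#' @param anchors A data frame with columns `index` (1..10) and `r`, `g`,
#'   `b` (integers 0-255), or a 10x3 numeric matrix of RGB rows. `NULL`
#'   uses the packaged default anchors.
#' @return A `monk_scale` object: a tibble with columns `index`, `r`, `g`,
#'   `b` and class `"monk_scale"`.
#' @examples
#' scale <- monk_scale()
#' interpolate_rgb(scale, c(1, 5.5, 10))
#' @export
monk_scale <- function(anchors = NULL) {
  if (is.null(anchors)) anchors <- monk_default_anchors()
  if (is.matrix(anchors)) {
    anchors <- tibble(
      index = seq_len(nrow(anchors)),
      r = anchors[, 1], g = anchors[, 2], b = anchors[, 3]
    )
  }
  anchors <- as_tibble(anchors)
  required <- c("index", "r", "g", "b")
  if (!all(required %in% names(anchors))) {
    abort("anchors must have columns index, r, g, b")
  }
  anchors <- arrange(anchors[required], .data$index)
  if (nrow(anchors) != 10L || !identical(as.integer(anchors$index), 1:10)) {
    abort("a Monk scale needs exactly 10 anchors with indices 1..10")
  }
  rgb <- as.matrix(anchors[, c("r", "g", "b")])
  if (any(!is.finite(rgb)) || any(rgb < 0) || any(rgb > 255)) {
    abort("anchor channels must be finite and within [0, 255]")
  }
  # scale must run light -> dark: compare rec. 709 luma of the end anchors
  luma <- c(0.2126, 0.7152, 0.0722)
  if (sum(rgb[1, ] * luma) <= sum(rgb[10, ] * luma)) {
    abort("anchor 1 must be lighter than anchor 10 (scale runs light to dark)")
  }
  structure(anchors, class = c("monk_scale", class(anchors)))
}

# Publicly documented Monk Skin Tone Scale sRGB anchors.
monk_default_anchors <- function() {
  hex <- c("#f6ede4", "#f3e7db", "#f7ead0", "#eadaba", "#d7bd96",
           "#a07e56", "#825c43", "#604134", "#3a312a", "#292420")
  rgb <- t(grDevices::col2rgb(hex))
  tibble(index = 1:10, r = as.numeric(rgb[, 1]),
         g = as.numeric(rgb[, 2]), b = as.numeric(rgb[, 3]))
}

#' @export
print.monk_scale <- function(x, ...) {
  cat("<monk_scale> 10 anchors, light -> dark\n")
  NextMethod()
}

scale_matrix <- function(scale) {
  if (!inherits(scale, "monk_scale")) scale <- monk_scale(scale)
  unname(as.matrix(scale[, c("r", "g", "b")]))
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

#' Interpolate a continuous Monk index to an sRGB colour
#'
#' Maps tone indices to real-valued sRGB triples by channel-wise linear
#' interpolation between adjacent scale anchors: for `n = floor(index)`,
#' the result is `C_n + (C_{n+1} - C_n) * (index - n)`. Indices are first
#' clamped to \[1, 10\]; an index of exactly 10 returns the darkest anchor.
#'
#' @param scale A [monk_scale()] object.
#' @param index Numeric vector of tone indices.
#' @return A tibble with columns `index`, `r`, `g`, `b` (real-valued
#'   channels, one row per index).
#' @export
interpolate_rgb <- function(scale, index) {
  rgb <- interpolate_rgb_matrix(scale, index)
  tibble(index = as.numeric(index), r = rgb[, 1], g = rgb[, 2], b = rgb[, 3])
}

interpolate_rgb_matrix <- function(scale, index) {
  if (!is.numeric(index) || any(!is.finite(index))) {
    abort("tone index must be finite numeric")
  }
  anchors <- scale_matrix(scale)
  x <- clamp(as.numeric(index), 1, 10)
  n <- pmin(floor(x), 9)           # floor(10) would address anchor 11
  frac <- x - n
  lo <- anchors[n, , drop = FALSE]
  hi <- anchors[n + 1, , drop = FALSE]
  out <- lo + (hi - lo) * frac
  dimnames(out) <- list(NULL, c("r", "g", "b"))
  out
}

#' Convert sRGB colours to CIELAB
#'
#' Closed-form sRGB (D65) to CIELAB conversion: gamma decoding, the sRGB
#' RGB-to-XYZ matrix, then the CIE L*a*b* transform against the D65
#' reference white. The float convention is used throughout the package:
#' L in \[0, 100\], a and b signed (roughly \[-128, 127\]).
#'
#' @param rgb An n x 3 matrix or data frame of sRGB channels in \[0, 255\]
#'   (a length-3 vector is taken as one colour).
#' @return A tibble with columns `l`, `a`, `b`.
#' @examples
#' rgb_to_lab(c(255, 255, 255)) # L = 100, a = b = 0
#' @export
rgb_to_lab <- function(rgb) {
  lab <- rgb_to_lab_matrix(rgb)
  tibble(l = lab[, 1], a = lab[, 2], b = lab[, 3])
}

rgb_to_lab_matrix <- function(rgb) {
  if (is.data.frame(rgb)) rgb <- as.matrix(rgb)
  if (is.null(dim(rgb))) rgb <- matrix(rgb, ncol = 3, byrow = TRUE)
  if (ncol(rgb) != 3) abort("rgb must have 3 channels")
  if (any(!is.finite(rgb)) || any(rgb < 0) || any(rgb > 255)) {
    abort("rgb channels must lie in [0, 255]")
  }
  v <- rgb / 255
  lin <- ifelse(v <= 0.04045, v / 12.92, ((v + 0.055) / 1.055)^2.4)
  m <- matrix(c(0.4124564, 0.3575761, 0.1804375,
                0.2126729, 0.7151522, 0.0721750,
                0.0193339, 0.1191920, 0.9503041),
              nrow = 3, byrow = TRUE)
  xyz <- lin %*% t(m)
  white <- c(0.95047, 1.00000, 1.08883)  # D65
  t3 <- sweep(xyz, 2, white, "/")
  delta <- 6 / 29
  f <- ifelse(t3 > delta^3, t3^(1 / 3), t3 / (3 * delta^2) + 4 / 29)
  lab <- cbind(
    l = 116 * f[, 2] - 16,
    a = 500 * (f[, 1] - f[, 2]),
    b = 200 * (f[, 2] - f[, 3])
  )
  unname(lab)
}

#' Map Monk tone indices directly to CIELAB colours
#'
#' Composition of [interpolate_rgb()] and [rgb_to_lab()]: interpolate the
#' continuous index to sRGB through the scale anchors, then convert to
#' CIELAB. This is the mapping the LAB error metric operates on.
#'
#' @inheritParams interpolate_rgb
#' @return A tibble with columns `index`, `l`, `a`, `b`.
#' @export
index_to_lab <- function(scale, index) {
  lab <- index_to_lab_matrix(scale, index)
  tibble(index = as.numeric(index), l = lab[, 1], a = lab[, 2], b = lab[, 3])
}

index_to_lab_matrix <- function(scale, index) {
  rgb_to_lab_matrix(interpolate_rgb_matrix(scale, index))
}

#' Euclidean distances between adjacent scale anchors
#'
#' The RGB-space distances between consecutive Monk anchor colours are
#' non-uniform; their mean summarises how unevenly the scale samples colour
#' space. For the packaged anchors the mean is about 41.1 units.
#'
#' @inheritParams interpolate_rgb
#' @return A tibble with columns `from_index`, `to_index`, `distance`
#'   (9 rows).
#' @export
adjacent_anchor_distances <- function(scale) {
  anchors <- scale_matrix(scale)
  d <- sqrt(rowSums((anchors[-1, , drop = FALSE] -
                       anchors[-10, , drop = FALSE])^2))
  tibble(from_index = 1:9, to_index = 2:10, distance = d)
}

#' Invert an sRGB colour to the nearest continuous Monk index
#'
#' Projects a colour onto each of the nine anchor segments of the scale and
#' returns the continuous index of the closest point. This is the geometric
#' inverse of [interpolate_rgb()]; on noiseless, identity-illuminant
#' renders it recovers the true tone from the face-core mean colour.
#'
#' @inheritParams interpolate_rgb
#' @param rgb An n x 3 matrix/data frame (or length-3 vector) of sRGB
#'   channels in \[0, 255\].
#' @return Numeric vector of tone indices in \[1, 10\].
#' @export
nearest_tone_index <- function(scale, rgb) {
  if (is.data.frame(rgb)) rgb <- as.matrix(rgb)
  if (is.null(dim(rgb))) rgb <- matrix(rgb, ncol = 3, byrow = TRUE)
  anchors <- scale_matrix(scale)
  vapply(seq_len(nrow(rgb)), function(i) {
    p <- rgb[i, ]
    best <- c(Inf, 1)
    for (k in 1:9) {
      a <- anchors[k, ]; b <- anchors[k + 1, ]
      seg <- b - a
      t <- clamp(sum((p - a) * seg) / sum(seg * seg), 0, 1)
      d2 <- sum((a + t * seg - p)^2)
      if (d2 < best[1]) best <- c(d2, k + t)
    }
    best[2]
  }, numeric(1))
}

#' Largest possible CIELAB distance under the package's convention
#'
#' The ceiling on any Euclidean LAB error: the space diagonal of the float
#' convention box, L in \[0, 100\] and a, b each spanning 255 units
#' (\[-128, 127\]). Evaluates to `sqrt(100^2 + 255^2 + 255^2)`, about 374.2.
#' An `"8bit"` convention (all axes scaled to \[0, 255\]) is also exposed
#' for comparison with 8-bit library output.
#'
#' @param convention `"float"` (default) or `"8bit"`.
#' @return A single number.
#' @export
max_lab_distance <- function(convention = c("float", "8bit")) {
  convention <- match.arg(convention)
  switch(convention,
    float = sqrt(100^2 + 255^2 + 255^2),
    "8bit" = sqrt(3 * 255^2)
  )
}

#' Read or write a Monk anchor table as CSV
#'
#' The CSV schema is `index,R,G,B` with one row per anchor.
#'
#' @param path File path.
#' @return `read_monk_anchors()` returns a [monk_scale()];
#'   `write_monk_anchors()` returns `path` invisibly.
#' @export
read_monk_anchors <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  names(df) <- tolower(names(df))
  monk_scale(df)
}

#' @rdname read_monk_anchors
#' @param scale A [monk_scale()] object.
#' @export
write_monk_anchors <- function(scale, path) {
  df <- as_tibble(scale)[, c("index", "r", "g", "b")]
  names(df) <- c("index", "R", "G", "B")
  readr::write_csv(df, path)
  invisible(path)
}
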