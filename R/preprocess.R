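#' Crop a face box with margin and resize
#'
#' The crop box is expanded by `margin` of its own width/height on every
#' side (a slight background allowance), clipped to the frame, then
#' resized to `side x side` with bilinear interpolation.
#'
#' @param image Numeric array `H x W x 3` (0..255).
#' @param box Face box, 0-based half-open `c(x0, y0, x1, y1)` with x =
#'   column and y = row.
#' @param margin Fraction of the box side added on each side (default 0.1).
#' @param side Output side in pixels (default 224).
#' @return Numeric array `side x side x 3`.
#' @export
crop_and_resize <- function(image, box, margin = 0.1, side = 224L) {
  d <- dim(image)
  if (length(box) != 4 || box[2] >= box[4] || box[1] >= box[3]) {
    abort("box must be a non-empty c(x0, y0, x1, y1)")
  }
  w <- box[3] - box[1]
  h <- box[4] - box[2]
  x0 <- max(floor(box[1] - margin * w), 0)
  y0 <- max(floor(box[2] - margin * h), 0)
  x1 <- min(ceiling(box[3] + margin * w), d[2])
  y1 <- min(ceiling(box[4] + margin * h), d[1])
  crop <- image[(y0 + 1):y1, (x0 + 1):x1, , drop = FALSE]
  resize_image(crop, side)
}

resize_image <- function(image, side) {
  side <- as.integer(side)
  if (dim(image)[1] == side && dim(image)[2] == side) {
    return(image * 1)  # drop integer storage for a uniform numeric contract
  }
  out <- array(0, c(side, side, dim(image)[3]))
  for (c_i in seq_len(dim(image)[3])) {
    out[, , c_i] <- EBImage::resize(image[, , c_i] * 1, w = side, h = side)
  }
  out
}

#' Flip an image
#'
#' @param image Array `H x W x C`.
#' @param mode `"none"`, `"h"` (horizontal, mirror columns), `"v"`
#'   (vertical, mirror rows), or `"hv"`.
#' @return Array of the same shape.
#' @export
flip_image <- function(image, mode = c("none", "h", "v", "hv")) {
  mode <- match.arg(mode)
  d <- dim(image)
  if (mode %in% c("h", "hv")) image <- image[, d[2]:1, , drop = FALSE]
  if (mode %in% c("v", "hv")) image <- image[d[1]:1, , , drop = FALSE]
  image
}

#' Quadruple a record set with horizontal/vertical flips
#'
#' Every record yields its original plus the horizontal, vertical and
#' combined flips, with labels copied, so the output has exactly four
#' times as many rows. The flip to apply is stored in a `flip` column and
#' honoured when tensors are prepared.
#'
#' @param records A manifest tibble.
#' @return The records tibble with a `flip` column, four rows per input
#'   row.
#' @export
augment_flips <- function(records) {
  if (nrow(records) < 1) abort("records must be non-empty")
  flips <- c("none", "h", "v", "hv")
  out <- records[rep(seq_len(nrow(records)), each = length(flips)), ]
  out$flip <- rep(flips, times = nrow(records))
  out
}

#' Grey-world colour balancing
#'
#' Under the Grey World Assumption the average scene colour is achromatic,
#' so each channel is rescaled by (mean over all channels) / (that
#' channel's mean). After the correction, and before clipping to
#' \[0, 255\], all channel means are equal.
#'
#' @param image Numeric array `H x W x 3` (0..255).
#' @return Numeric array of the same shape, clipped to \[0, 255\].
#' @export
grey_world_balance <- function(image) {
  if (length(image) == 0) abort("image must be non-empty")
  ch_means <- apply(image, 3, mean)
  if (any(ch_means <= .Machine$double.eps)) {
    abort("grey-world balance undefined for a zero-mean channel")
  }
  target <- mean(ch_means)
  out <- image * 1
  for (c_i in 1:3) out[, , c_i] <- image[, , c_i] * (target / ch_means[c_i])
  clamp(out, 0, 255)
}

#' Randomly permute pixel positions
#'
#' Applies one uniform random permutation to pixel positions; whole RGB
#' triples move together, so the image's colour multiset (and hence every
#' per-channel histogram and the mean colour) is preserved exactly while
#' all spatial structure is destroyed.
#'
#' @param image Array `H x W x C`.
#' @param seed Integer seed; the permutation is deterministic given it.
#' @return Array of the same shape.
#' @export
shuffle_pixels <- function(image, seed = 1L) {
  d <- dim(image)
  n <- d[1] * d[2]
  perm <- withr::with_seed(as.integer(seed), sample.int(n))
  out <- image * 1
  for (c_i in seq_len(d[3])) {
    ch <- image[, , c_i]
    out[, , c_i] <- matrix(ch[perm], d[1], d[2])
  }
  out
}

#' Input tensor specification
#'
#' @param colour_mode `"LAB"` (default), `"RGB"`, or `"RGB_HSV_LAB"` (the
#'   9-channel concatenation).
#' @param side Input side in pixels (default 224).
#' @return A list with `colour_mode`, `side` and the implied `channels`
#'   (9 iff `RGB_HSV_LAB`, else 3).
#' @export
input_tensor_spec <- function(colour_mode = c("LAB", "RGB", "RGB_HSV_LAB"),
                              side = 224L) {
  colour_mode <- match.arg(colour_mode)
  list(colour_mode = colour_mode, side = as.integer(side),
       channels = if (colour_mode == "RGB_HSV_LAB") 9L else 3L)
}

#' Convert an image to a model input tensor
#'
#' Produces a channel-first array in the requested colour mode. Channel
#' scaling is fixed: R, G, B and H, S, V are scaled to \[0, 1\]; L is
#' divided by 100 and a, b are mapped from \[-128, 127\] to \[0, 1\].
#' In 9-channel mode the order is R, G, B, H, S, V, L, a, b.
#'
#' @param image Numeric array `H x W x 3` of 8-bit RGB values (0..255).
#' @param spec An [input_tensor_spec()]; the image is resized to
#'   `spec$side` first if needed.
#' @return Numeric array `channels x side x side`.
#' @export
to_input_tensor <- function(image, spec = input_tensor_spec()) {
  if (!is.list(spec) || is.null(spec$colour_mode)) {
    abort("spec must be an input_tensor_spec()")
  }
  image <- resize_image(image, spec$side)
  h <- dim(image)[1]; w <- dim(image)[2]
  rgb_flat <- cbind(as.vector(image[, , 1]), as.vector(image[, , 2]),
                    as.vector(image[, , 3]))
  planes <- switch(spec$colour_mode,
    RGB = rgb_flat / 255,
    LAB = scale_lab(rgb_to_lab_matrix(clamp(rgb_flat, 0, 255))),
    RGB_HSV_LAB = cbind(
      rgb_flat / 255,
      t(grDevices::rgb2hsv(t(clamp(rgb_flat, 0, 255)), maxColorValue = 255)),
      scale_lab(rgb_to_lab_matrix(clamp(rgb_flat, 0, 255)))
    ),
    abort(paste0("unknown colour mode '", spec$colour_mode, "'"))
  )
  out <- array(0, c(ncol(planes), h, w))
  for (c_i in seq_len(ncol(planes))) {
    out[c_i, , ] <- matrix(planes[, c_i], h, w)
  }
  out
}

scale_lab <- function(lab) {
  cbind(lab[, 1] / 100, (lab[, 2] + 128) / 255, (lab[, 3] + 128) / 255)
}

#' Partition a manifest into training and validation sets
#'
#' In `non_mixed` mode identities are partitioned, so no person appears in
#' both sides (`floor(train_fraction * n_identities)` identities go to
#' train). In `mixed` mode individual images are partitioned irrespective
#' of identity (`floor(train_fraction * n_images)` to train), so the same
#' identity can appear in both sides under different conditions.
#'
#' @param manifest A manifest tibble with `identity_id`.
#' @param train_fraction Fraction assigned to training (default 0.65).
#' @param mode `"non_mixed"` (default) or `"mixed"`.
#' @param seed Integer seed; the partition is deterministic given it.
#' @return The manifest with its `split` column filled with
#'   `"train"`/`"val"`.
#' @export
split_identities <- function(manifest, train_fraction = 0.65,
                             mode = c("non_mixed", "mixed"), seed = 1L) {
  mode <- match.arg(mode)
  if (nrow(manifest) < 1) abort("manifest must be non-empty")
  if (train_fraction <= 0 || train_fraction >= 1) {
    abort("train_fraction must lie strictly between 0 and 1")
  }
  if (mode == "non_mixed") {
    ids <- sort(unique(manifest$identity_id))
    n_train <- floor(train_fraction * length(ids))
    if (n_train < 1 || n_train >= length(ids)) {
      abort("degenerate split: one side would be empty")
    }
    shuffled <- withr::with_seed(as.integer(seed), sample(ids))
    train_ids <- shuffled[seq_len(n_train)]
    manifest$split <- ifelse(manifest$identity_id %in% train_ids,
                             "train", "val")
  } else {
    n <- nrow(manifest)
    n_train <- floor(train_fraction * n)
    if (n_train < 1 || n_train >= n) {
      abort("degenerate split: one side would be empty")
    }
    idx <- withr::with_seed(as.integer(seed), sample.int(n))
    manifest$split <- "val"
    manifest$split[idx[seq_len(n_train)]] <- "train"
  }
  manifest
}

#' Prepare a batch tensor from manifest records
#'
#' Runs the deterministic preprocessing pipeline for every record: render
#' (or read) the image, optionally grey-world balance, optionally shuffle
#' pixels (per-image seeds derived from `shuffle_seed`), crop the
#' ground-truth face box with margin, resize, apply the record's flip (if
#' an `augment_flips()` column is present), and convert to the requested
#' colour channels.
#'
#' @param records Manifest tibble (optionally augmented with `flip`).
#' @param spec An [input_tensor_spec()].
#' @param grey_world Apply [grey_world_balance()] (default `FALSE`).
#' @param shuffle Apply [shuffle_pixels()] (default `FALSE`).
#' @param shuffle_seed Base seed for per-image shuffle permutations.
#' @param crop Crop to the face box before resizing (default `TRUE`).
#' @param margin Crop margin fraction (default 0.1).
#' @param image_dir Directory holding the rendered PNGs; `NULL` (default)
#'   re-renders images from the manifest's rendering columns.
#' @param scale The [monk_scale()] for re-rendering.
#' @return A list: `x`, a numeric array `side x side x n x channels`
#'   (height, width, record, channel), and `y`, the numeric tone targets.
#' @export
prepare_tensors <- function(records, spec = input_tensor_spec(),
                            grey_world = FALSE, shuffle = FALSE,
                            shuffle_seed = 1L, crop = TRUE, margin = 0.1,
                            image_dir = NULL, scale = monk_scale()) {
  n <- nrow(records)
  if (n < 1) abort("records must be non-empty")
  x <- array(0, c(spec$side, spec$side, n, spec$channels))
  for (i in seq_len(n)) {
    rec <- records[i, ]
    img <- if (!is.null(image_dir)) {
      png::readPNG(file.path(image_dir, rec$image_path)) * 255
    } else {
      render_record(rec, scale = scale)
    }
    if (grey_world) img <- grey_world_balance(img)
    flip <- rec_field(rec, "flip", "none")
    if (shuffle) {
      img <- shuffle_pixels(img, derive_seed(shuffle_seed, rec$image_path,
                                             flip))
    }
    if (crop && "centre_x" %in% names(rec)) {
      box <- face_mask(rec, rec$rotation,
                       rec_field(rec, "size", dim(img)[1]))$box
      img <- crop_and_resize(img, box, margin = margin, side = spec$side)
    }
    tensor <- to_input_tensor(img, spec)        # channels x side x side
    for (c_i in seq_len(spec$channels)) {
      plane <- tensor[c_i, , ]
      if (flip %in% c("h", "hv")) plane <- plane[, ncol(plane):1]
      if (flip %in% c("v", "hv")) plane <- plane[nrow(plane):1, ]
      x[, , i, c_i] <- plane
    }
  }
  list(x = x, y = as.numeric(records$true_tone))
}
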