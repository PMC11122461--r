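test_that("crop arithmetic expands the box by the margin then resizes", {
  img <- array(runif(200 * 200 * 3, 0, 255), c(200, 200, 3))
  # full-frame box, no margin, matching side: identity
  out <- crop_and_resize(img, c(0, 0, 200, 200), margin = 0, side = 200)
  expect_equal(out, img * 1)
  # 100x100 centre box with margin 0.1 -> 120x120 crop before resize
  out2 <- crop_and_resize(img, c(50, 50, 150, 150), margin = 0.1, side = 120)
  expect_equal(out2, img[41:160, 41:160, ] * 1)
  expect_error(crop_and_resize(img, c(10, 10, 10, 40)), "box")
})

test_that("cropped synthetic faces are dominated by face pixels", {
  id <- fixture_identity(tone = 4)
  img <- render_image(id, neutral_condition(), "front", 128, noise_sigma = 0)
  m <- face_mask(id, "front", 128)
  box <- m$box
  face_frac_crop <- function(margin) {
    mask3 <- array(rep(m$face, 3), c(128, 128, 3))
    crop <- crop_and_resize(mask3 * 255, box, margin = margin, side = 64)
    mean(crop[, , 1] > 127)
  }
  expect_gt(face_frac_crop(0.1), 0.5)
  expect_gt(face_frac_crop(0), face_frac_crop(0.1))
})

test_that("flip augmentation quadruples records and flips are involutive", {
  records <- build_dataset(2, conditions = lighting_conditions()[1, ],
                           rotations = "front", seed = 1, size = 32)
  out <- augment_flips(records)
  expect_equal(nrow(out), 4 * nrow(records))
  expect_equal(sort(unique(out$flip)), sort(c("none", "h", "v", "hv")))
  expect_error(augment_flips(records[0, ]), "non-empty")

  img <- array(runif(32 * 32 * 3), c(32, 32, 3))
  expect_equal(flip_image(flip_image(img, "h"), "h"), img)
  expect_equal(flip_image(flip_image(img, "v"), "v"), img)
  expect_equal(flip_image(flip_image(img, "hv"), "hv"), img)
  uniform <- array(3, c(8, 8, 3))
  for (mode in c("h", "v", "hv")) {
    expect_equal(flip_image(uniform, mode), uniform)
  }
})

test_that("grey-world balancing equalises channel means", {
  g <- array(117, c(10, 10, 3))
  expect_equal(grey_world_balance(g), g)

  img <- array(0, c(4, 4, 3))
  img[, , 1] <- 100; img[, , 2] <- 120; img[, , 3] <- 140
  out <- grey_world_balance(img)
  expect_equal(apply(out, 3, mean), rep(120, 3))

  # hand-computed 2-pixel example: gains (2, 1, 2/3)
  two <- array(0, c(1, 2, 3))
  two[1, , 1] <- 60; two[1, , 2] <- 120; two[1, , 3] <- 180
  out2 <- grey_world_balance(two)
  expect_equal(as.vector(out2), rep(120, 6))

  zero <- array(0, c(2, 2, 3))
  expect_error(grey_world_balance(zero), "zero-mean")
})

test_that("grey-world correction is idempotent before clipping", {
  withr::with_seed(8, img <- array(runif(300, 20, 200), c(10, 10, 3)))
  once <- grey_world_balance(img)
  expect_equal(grey_world_balance(once), once, tolerance = 1e-12)
})

test_that("pixel shuffling permutes positions but preserves colour content", {
  one <- array(c(10, 20, 30), c(1, 1, 3))
  expect_equal(shuffle_pixels(one, 1), one * 1)

  withr::with_seed(9, img <- array(sample(0:255, 300, TRUE), c(10, 10, 3)))
  out <- shuffle_pixels(img, seed = 42)
  for (c_i in 1:3) {
    expect_equal(sort(as.vector(out[, , c_i])),
                 sort(as.vector(img[, , c_i])))
  }
  # whole triples move together: joint colour multiset preserved
  as_triples <- function(x) {
    sort(paste(x[, , 1], x[, , 2], x[, , 3], sep = "/"))
  }
  expect_equal(as_triples(out), as_triples(img))
  expect_equal(apply(out, 3, mean), apply(img, 3, mean))

  expect_identical(shuffle_pixels(img, 42), out)
  expect_false(identical(shuffle_pixels(img, 43), out))
})

test_that("input tensors carry the documented channels and scaling", {
  white <- array(255, c(16, 16, 3))
  lab <- to_input_tensor(white, input_tensor_spec("LAB", 16))
  expect_equal(dim(lab), c(3, 16, 16))
  expect_equal(mean(lab[1, , ]), 1, tolerance = 1e-4)        # L at max
  expect_equal(mean(lab[2, , ]), 128 / 255, tolerance = 1e-3) # a neutral
  expect_equal(mean(lab[3, , ]), 128 / 255, tolerance = 1e-3) # b neutral

  withr::with_seed(10, img <- array(sample(0:255, 16 * 16 * 3, TRUE),
                                    c(16, 16, 3)))
  nine <- to_input_tensor(img, input_tensor_spec("RGB_HSV_LAB", 16))
  expect_equal(dim(nine), c(9, 16, 16))
  for (c_i in 1:3) {
    expect_equal(nine[c_i, , ], img[, , c_i] / 255)
  }
  expect_error(to_input_tensor(img, list(colour_mode = "XYZ", side = 16L,
                                         channels = 3L)), "colour mode")
})

test_that("identity splits follow the floor rule and stay disjoint", {
  mf <- build_dataset(20, conditions = lighting_conditions()[1:3, ],
                      rotations = "front", seed = 6, size = 32)
  split <- split_identities(mf, 0.65, "non_mixed", seed = 1)
  train_ids <- unique(split$identity_id[split$split == "train"])
  val_ids <- unique(split$identity_id[split$split == "val"])
  expect_equal(length(train_ids), 13)  # floor(0.65 * 20)
  expect_equal(length(val_ids), 7)
  expect_length(intersect(train_ids, val_ids), 0)
  expect_identical(split_identities(mf, 0.65, "non_mixed", seed = 1), split)

  mixed <- split_identities(mf, 0.65, "mixed", seed = 1)
  expect_equal(sum(mixed$split == "train"), floor(0.65 * nrow(mf)))
  overlap <- intersect(unique(mixed$identity_id[mixed$split == "train"]),
                       unique(mixed$identity_id[mixed$split == "val"]))
  expect_gt(length(overlap), 0)

  expect_error(split_identities(mf, 0.001, "non_mixed"), "degenerate")
  expect_error(split_identities(mf[0, ], 0.65), "non-empty")
})

test_that("prepared tensors honour flips and stay deterministic", {
  records <- build_dataset(2, conditions = lighting_conditions()[2, ],
                           rotations = "front", seed = 31, size = 32)
  spec <- input_tensor_spec("RGB", 32)
  plain <- prepare_tensors(records, spec)
  expect_equal(dim(plain$x), c(32, 32, 2, 3))
  expect_equal(plain$y, records$true_tone)

  aug <- prepare_tensors(augment_flips(records[1, ]), spec)
  expect_equal(dim(aug$x)[3], 4)
  # h-flip of the prepared plane equals the plane of the h-flip record
  expect_equal(aug$x[, 32:1, 2, 1], aug$x[, , 1, 1])
  expect_equal(prepare_tensors(records, spec)$x, plain$x)
})
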