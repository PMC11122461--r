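test_that("tone distances are absolute element-wise differences", {
  expect_equal(class_distances(3.2, 3.0), 0.2)
  expect_equal(class_distances(c(1, 5, 9), c(1, 5, 9)), c(0, 0, 0))
  expect_equal(class_distances(c(1, 10), c(10, 1)), c(9, 9))
  expect_error(class_distances(1:3, 1:2), "equal length")
})

test_that("threshold accuracy counts ties as hits", {
  expect_equal(accuracy_at(rep(0, 5), 0.5), 100)
  expect_equal(accuracy_at(c(0.2, 0.4, 0.6, 1.2), 0.5), 50)
  expect_equal(accuracy_at(c(0.3, 0.7), 0.1), 0)
  expect_equal(accuracy_at(c(0.5, 0.5), 0.5), 100)  # tie rule
  expect_equal(accuracy_at(c(0.1, 2), Inf), 100)
  expect_error(accuracy_at(numeric(0), 1), "non-empty")
  expect_error(accuracy_at(1, -1), ">= 0")
})

test_that("the accuracy distribution walks the 0.1-step threshold grid", {
  ad <- accuracy_distribution(rep(0, 3), n_max = 5)
  expect_equal(ad$accuracy, rep(100, 6))
  expect_equal(ad$threshold, (0:5) * 0.1)

  ad2 <- accuracy_distribution(c(0.05, 0.15), n_max = 2)
  expect_equal(ad2$accuracy, c(0, 50, 100))

  withr::with_seed(13, {
    for (i in 1:20) {
      d <- abs(rnorm(50, 0, 2))
      n_max <- ceiling(max(d) / 0.1) + 1
      acc <- accuracy_distribution(d, n_max)$accuracy
      expect_true(all(diff(acc) >= 0))
      expect_equal(acc[n_max + 1], 100)  # grid now exceeds max distance
    }
  })
})

test_that("LAB error statistics use population variance", {
  s <- monk_scale()
  same <- lab_errors(c(2, 5, 8), c(2, 5, 8), s)
  expect_equal(same$mu, 0)
  expect_equal(same$sigma, 0)

  single <- lab_errors(4.2, 6.9, s)
  expect_equal(single$sigma, 0)
  expect_gt(single$mu, 0)

  # two pairs with known distances 3 and 5 -> mu 4, sigma 1 (divide by N)
  d <- c(3, 5)
  mu <- mean(d)
  expect_equal(sqrt(mean((d - mu)^2)), 1)
  two <- lab_errors(c(1, 1), c(1.05, 1.2), s)
  manual <- oracle_lab_errors(c(1, 1), c(1.05, 1.2), s)
  expect_equal(two$mu, manual$mu)
  expect_equal(two$sigma, manual$sigma)
})

test_that("vectorised metrics agree with loop-based oracles on random batches", {
  s <- monk_scale()
  withr::with_seed(17, {
    for (i in 1:1000) {
      n <- sample(1:30, 1)
      est <- runif(n, 1, 10)
      tgt <- runif(n, 1, 10)
      thr <- runif(1, 0, 3)
      d <- class_distances(est, tgt)
      expect_equal(accuracy_at(d, thr), oracle_accuracy_at(d, thr),
                   tolerance = 1e-9)
    }
    for (i in 1:50) {
      est <- runif(6, 1, 10)
      tgt <- runif(6, 1, 10)
      got <- lab_errors(est, tgt, s)
      want <- oracle_lab_errors(est, tgt, s)
      expect_equal(got$distances, want$d, tolerance = 1e-9)
      expect_equal(got$mu, want$mu, tolerance = 1e-9)
      expect_equal(got$sigma, want$sigma, tolerance = 1e-9)
    }
  })
})

test_that("LAB errors never exceed the documented space-diagonal ceiling", {
  s <- monk_scale()
  withr::with_seed(19, {
    est <- runif(500, 1, 10)
    tgt <- runif(500, 1, 10)
    expect_lt(max(lab_errors(est, tgt, s)$distances), max_lab_distance())
  })
  # the ceiling itself sits within 1% of 374.17
  expect_lt(abs(max_lab_distance() - 374.17) / 374.17, 0.01)
})

test_that("classification accuracy averages batches unweighted by default", {
  onehot <- function(k, n = 10) {
    m <- matrix(0, length(k), n)
    m[cbind(seq_along(k), k)] <- 1
    m
  }
  expect_equal(classification_accuracy(list(onehot(c(1, 5))), list(c(1, 5))),
               100)
  # 100% and 0% batches average to 50 regardless of batch sizes
  p <- list(onehot(c(2, 2, 2)), onehot(7))
  t_all <- list(c(2, 2, 2), 3)
  expect_equal(classification_accuracy(p, t_all), 50)
  # sizes 3 (all correct) and 1 (wrong): 50 unweighted, 75 weighted
  expect_equal(classification_accuracy(p, t_all, weighted = TRUE), 75)
  expect_error(classification_accuracy(list(), list()), "non-empty")
})

test_that("evaluation reports partition records into groups and lights", {
  df <- tibble::tibble(
    estimate = c(1.2, 2.0, 4.4, 6.1, 8.0, 9.9),
    true_tone = c(1.0, 2.5, 4.0, 6.5, 8.2, 9.5),
    light_type = rep(c("led_warm", "halogen_warm"), 3)
  )
  rep_out <- eval_report(df)
  tab <- tidy(rep_out)
  ns <- dplyr::filter(tab, scope == "tone_group", metric == "n")
  expect_equal(sum(ns$value), nrow(df))

  # per-group means match a brute-force recomputation
  for (g in unique(ns$group[ns$value > 0])) {
    sel <- monktone:::tone_group(df$true_tone) == g
    want <- oracle_lab_errors(df$estimate[sel], df$true_tone[sel],
                              monk_scale())$mu
    got <- dplyr::filter(tab, scope == "tone_group", group == g,
                         metric == "lab_mu")$value
    expect_equal(got, want, tolerance = 1e-9)
  }

  # batches confined to one group flag the others as empty
  low <- tibble::tibble(estimate = c(1, 2), true_tone = c(1.4, 2.2))
  tab_low <- tidy(eval_report(low, light = NULL))
  empty_n <- dplyr::filter(tab_low, scope == "tone_group",
                           group != "group1_tones_1_3", metric == "n")
  expect_equal(empty_n$value, c(0, 0))

  expect_error(eval_report(df, light = "missing_col"), "not found")
  expect_error(eval_report(dplyr::select(df, -estimate)), "not found")
})

test_that("group assignment rounds half-up at the 3/4 and 7/8 boundaries", {
  expect_equal(monktone:::tone_group(c(3.4, 3.5, 7.4, 7.5)),
               c("group1_tones_1_3", "group2_tones_4_7",
                 "group2_tones_4_7", "group3_tones_8_10"))
})

test_that("report glance exposes headline accuracy and error metrics", {
  df <- tibble::tibble(estimate = c(5, 6), true_tone = c(5.2, 6.9))
  g <- glance(eval_report(df, light = NULL))
  expect_named(g, c("accuracy_0.5", "accuracy_1", "accuracy_2",
                    "lab_mu", "lab_sigma", "n"))
  expect_equal(g$accuracy_0.5, 50)
  expect_equal(g$n, 2)
})
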