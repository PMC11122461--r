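#' Estimated-to-target tone distances
#'
#' Element-wise absolute differences between estimated and target Monk
#' tone indices. The signed differences carry no extra information for
#' the threshold-accuracy metric, which counts distances below a
#' threshold, so distances are reported as absolute values.
#'
#' @param estimates,targets Equal-length numeric vectors of tone indices.
#' @return Numeric vector of distances.
#' @export
class_distances <- function(estimates, targets) {
  if (length(estimates) != length(targets) || length(estimates) < 1) {
    abort("estimates and targets must be non-empty and of equal length")
  }
  abs(estimates - targets)
}

#' Accuracy at a threshold distance
#'
#' The percentage of samples whose estimated-to-target distance is at most
#' the threshold (ties count as hits; exact ties are measure-zero for
#' continuous model outputs).
#'
#' @param distances Non-empty numeric vector of distances.
#' @param threshold Non-negative threshold.
#' @return A percentage in \[0, 100\].
#' @export
accuracy_at <- function(distances, threshold) {
  if (length(distances) < 1) abort("distances must be non-empty")
  if (threshold < 0) abort("threshold must be >= 0")
  100 * sum(distances <= threshold) / length(distances)
}

#' Accuracy distribution over incremental thresholds
#'
#' Evaluates [accuracy_at()] on the threshold grid `n * 0.1` for
#' `n = 0..n_max`, yielding the cumulative accuracy curve that
#' summarises an estimator at every tolerance simultaneously. The curve
#' is non-decreasing and reaches 100 once the threshold exceeds the
#' largest distance.
#'
#' @param distances Non-empty numeric vector of distances.
#' @param n_max Largest threshold step (default 90, i.e. threshold 9).
#' @return An `accuracy_distribution` tibble with columns `n`,
#'   `threshold`, `accuracy`.
#' @export
accuracy_distribution <- function(distances, n_max = 90L) {
  if (n_max < 1) abort("n_max must be >= 1")
  n <- 0:n_max
  acc <- vapply(n, function(k) accuracy_at(distances, k * 0.1), numeric(1))
  structure(tibble(n = n, threshold = n * 0.1, accuracy = acc),
            class = c("accuracy_distribution", class(tibble())))
}

#' LAB-space error statistics for tone estimates
#'
#' Maps estimates and targets to CIELAB through the Monk scale
#' ([index_to_lab()]), takes Euclidean distances per pair, and summarises
#' them by the mean and the population standard deviation (divide by N,
#' no Bessel correction).
#'
#' @param estimates,targets Equal-length numeric tone-index vectors.
#' @param scale A [monk_scale()].
#' @return A `lab_error_report` list: `distances`, `mu`, `sigma`, `n`.
#' @export
lab_errors <- function(estimates, targets, scale = monk_scale()) {
  if (length(estimates) != length(targets) || length(estimates) < 1) {
    abort("estimates and targets must be non-empty and of equal length")
  }
  lab_est <- index_to_lab_matrix(scale, estimates)
  lab_tgt <- index_to_lab_matrix(scale, targets)
  d <- sqrt(rowSums((lab_est - lab_tgt)^2))
  mu <- mean(d)
  structure(list(distances = d, mu = mu,
                 sigma = sqrt(mean((d - mu)^2)), n = length(d)),
            class = "lab_error_report")
}

#' @export
print.lab_error_report <- function(x, ...) {
  cat(sprintf("<lab_error_report> %.2f +/- %.2f (n = %d)\n",
              x$mu, x$sigma, x$n))
  invisible(x)
}

#' Batch-averaged classification accuracy
#'
#' For each batch, the percentage of samples whose argmax class matches
#' the target; the final figure is the unweighted mean over batches.
#' `weighted = TRUE` instead pools all samples (sample-weighted).
#'
#' @param prob_batches List of probability matrices (rows = samples,
#'   10 columns).
#' @param target_batches List of integer class vectors (1..10), aligned
#'   with `prob_batches`.
#' @param weighted Use sample-weighted pooling instead of the unweighted
#'   batch mean.
#' @return A percentage.
#' @export
classification_accuracy <- function(prob_batches, target_batches,
                                    weighted = FALSE) {
  if (length(prob_batches) < 1 ||
      length(prob_batches) != length(target_batches)) {
    abort("prob_batches and target_batches must be non-empty and aligned")
  }
  hits <- purrr::map2(prob_batches, target_batches, function(p, y) {
    if (nrow(p) != length(y)) abort("batch sizes must agree")
    max.col(p, ties.method = "first") == y
  })
  if (weighted) {
    100 * mean(unlist(hits))
  } else {
    100 * mean(vapply(hits, mean, numeric(1)))
  }
}

tone_group <- function(tone) {
  k <- clamp(floor(tone + 0.5), 1, 10)  # round half up to integer tone
  dplyr::case_when(
    k <= 3 ~ "group1_tones_1_3",
    k <= 7 ~ "group2_tones_4_7",
    TRUE ~ "group3_tones_8_10"
  )
}

report_cell <- function(est, tgt, scale, thresholds) {
  d <- class_distances(est, tgt)
  lab <- lab_errors(est, tgt, scale)
  bind_rows(
    tibble(metric = sprintf("accuracy_%g", thresholds),
           value = vapply(thresholds, function(t) accuracy_at(d, t),
                          numeric(1))),
    tibble(metric = c("lab_mu", "lab_sigma"), value = c(lab$mu, lab$sigma)),
    tibble(metric = "n", value = length(est))
  )
}

#' Full evaluation report for a batch of tone estimates
#'
#' Computes threshold accuracies and LAB error statistics overall, per
#' light type (when a light column is present) and per skin-tone group
#' (tones 1-3, 4-7, 8-10, assigned by rounding the target tone half-up to
#' the nearest integer).
#'
#' @param data A data frame holding estimates and targets (and optionally
#'   a light-type column).
#' @param estimate,truth,light Column names (strings) for the estimated
#'   tone, target tone, and light type (`light = NULL` skips the
#'   per-light breakdown).
#' @param scale A [monk_scale()].
#' @param thresholds Accuracy thresholds (default `c(0.5, 1, 2)`).
#' @return A `monk_eval_report`: a long tibble with columns `scope`,
#'   `group`, `metric`, `value` wrapped with accessors; use [tidy()] for
#'   the tibble and [glance()] for the headline row.
#' @export
eval_report <- function(data, estimate = "estimate", truth = "true_tone",
                        light = "light_type", scale = monk_scale(),
                        thresholds = c(0.5, 1, 2)) {
  if (!estimate %in% names(data) || !truth %in% names(data)) {
    abort("estimate/truth columns not found in data")
  }
  est <- data[[estimate]]
  tgt <- data[[truth]]
  rows <- list(
    mutate(report_cell(est, tgt, scale, thresholds),
           scope = "overall", group = "all")
  )
  if (!is.null(light)) {
    if (!light %in% names(data)) {
      abort(sprintf("light column '%s' not found in data", light))
    }
    for (lt in sort(unique(data[[light]]))) {
      sel <- data[[light]] == lt
      rows <- c(rows, list(
        mutate(report_cell(est[sel], tgt[sel], scale, thresholds),
               scope = "light_type", group = lt)
      ))
    }
  }
  groups <- tone_group(tgt)
  for (g in c("group1_tones_1_3", "group2_tones_4_7", "group3_tones_8_10")) {
    sel <- groups == g
    if (any(sel)) {
      rows <- c(rows, list(
        mutate(report_cell(est[sel], tgt[sel], scale, thresholds),
               scope = "tone_group", group = g)
      ))
    } else {
      rows <- c(rows, list(tibble(metric = "n", value = 0,
                                  scope = "tone_group", group = g)))
    }
  }
  out <- bind_rows(rows)[, c("scope", "group", "metric", "value")]
  structure(list(table = out, thresholds = thresholds),
            class = "monk_eval_report")
}

#' @export
print.monk_eval_report <- function(x, ...) {
  overall <- filter(x$table, .data$scope == "overall")
  cat("<monk_eval_report>\n")
  for (i in seq_len(nrow(overall))) {
    cat(sprintf("  %s: %.2f\n", overall$metric[i], overall$value[i]))
  }
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.monk_eval_report <- function(x, ...) x$table

#' @exportS3Method generics::glance
glance.monk_eval_report <- function(x, ...) {
  overall <- filter(x$table, .data$scope == "overall")
  out <- as.list(overall$value)
  names(out) <- overall$metric
  as_tibble(out)
}
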