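#' Empirical motif p-value
#'
#' The fraction of null replicates in which the query occurs at least as
#' often as in the real network. Lower values mean a more significant motif.
#' A reported 0 only bounds the p-value: with `add_one = TRUE` the
#' `(k + 1) / (r + 1)` convention is used instead, which is bounded below by
#' `1 / (r + 1)`.
#'
#' @param random_counts integer vector of per-replicate occurrence counts.
#' @param real_count occurrence count in the real network.
#' @param add_one use the add-one (pseudo-count) convention? Default `FALSE`,
#'   the literal empirical fraction.
#' @return a number in `[0, 1]`.
#' @export
p_value <- function(random_counts, real_count, add_one = FALSE) {
  if (length(random_counts) < 1) abort("need at least one replicate count")
  k <- sum(random_counts >= real_count)
  r <- length(random_counts)
  if (add_one) (k + 1) / (r + 1) else k / r
}

#' Motif z-score
#'
#' `(real_count - mean(random_counts)) / sd(random_counts)`. Strongly
#' positive values flag the query as over-represented. When the replicate
#' counts have zero spread the z-score is undefined and `NA` is returned
#' (with a warning), not an error.
#'
#' @inheritParams p_value
#' @param sd_type `"sample"` (divisor `r - 1`, the default) or
#'   `"population"` (divisor `r`).
#' @return a number, or `NA` when the null standard deviation is zero.
#' @export
z_score <- function(random_counts, real_count,
                    sd_type = c("sample", "population")) {
  sd_type <- match.arg(sd_type)
  if (length(random_counts) < 2) abort("need at least two replicate counts")
  mu <- mean(random_counts)
  s <- sd(random_counts)
  if (sd_type == "population") {
    s <- s * sqrt((length(random_counts) - 1) / length(random_counts))
  }
  if (is.na(s) || s == 0) {
    warn("null counts have zero standard deviation; z-score undefined")
    return(NA_real_)
  }
  (real_count - mu) / s
}

#' Test a query's significance as a network motif
#'
#' Counts the query's occurrences in the target, generates `r` null-model
#' replicates (replicate `i` is seeded with `seed + i`, so runs are
#' reproducible and replicates independent), counts occurrences in each, and
#' summarizes with the empirical p-value and the z-score. Queries carrying
#' wildcards are handled transparently; queries with path constraints go
#' through the approximate matcher.
#'
#' @param query a query graph.
#' @param target a labeled graph of the same directedness.
#' @param config a [model_config()]; `NULL` estimates every parameter of
#'   `model` from the target via [estimate_params()].
#' @param model model name used when `config` is `NULL`.
#' @param r number of replicates, between 1 and 100 unless
#'   `allow_large = TRUE`.
#' @param seed integer base seed.
#' @param sd_type standard-deviation convention for the z-score.
#' @param allow_large lift the GUI-inherited `r <= 100` bound.
#' @return an object of class `motif_significance` with fields `real_count`,
#'   `random_counts`, `mean`, `sd`, `p_value`, `z_score`, `model`, `r`,
#'   `seed`. Has [tidy()], [glance()], [autoplot()] and `print` methods.
#' @export
run_significance <- function(query, target, config = NULL,
                             model = "shuffling", r = 20, seed = 1,
                             sd_type = c("sample", "population"),
                             allow_large = FALSE) {
  sd_type <- match.arg(sd_type)
  if (r < 1) abort("r must be at least 1 (no test is possible with r = 0)")
  if (r > 100 && !allow_large) {
    abort("r > 100; pass allow_large = TRUE to exceed the default bound")
  }
  if (is.null(config)) config <- estimate_params(model, target, seed = seed)
  count_fn <- function(q, g) count_occurrences(q, g)
  real <- count_fn(query, target)
  counts <- vapply(seq_len(r), function(i) {
    replica <- generate_null(target, config, seed = as.integer(seed) + i)
    count_fn(query, replica)
  }, 0L)
  mu <- mean(counts)
  s <- sd(counts)
  z <- if (r >= 2 && !is.na(s) && s > 0) {
    z_score(counts, real, sd_type = sd_type)
  } else {
    NA_real_
  }
  structure(list(real_count = real, random_counts = counts, mean = mu,
                 sd = s, p_value = p_value(counts, real), z_score = z,
                 model = config$model, config = config, r = r,
                 seed = as.integer(seed), sd_type = sd_type),
            class = "motif_significance")
}

#' @export
print.motif_significance <- function(x, ...) {
  cat("Motif significance test\n")
  cat(sprintf("  null model : %s (r = %d, seed = %d)\n", x$model, x$r, x$seed))
  cat(sprintf("  real count : %d\n", x$real_count))
  cat(sprintf("  null mean  : %.3f (sd %.3f)\n", x$mean, x$sd))
  cat(sprintf("  p-value    : %.4g\n", x$p_value))
  if (is.na(x$z_score)) {
    cat("  z-score    : undefined (zero null standard deviation)\n")
  } else {
    cat(sprintf("  z-score    : %.4f\n", x$z_score))
  }
  invisible(x)
}

#' Per-replicate view of a significance test
#'
#' @param x a `motif_significance` object.
#' @param ... unused.
#' @return a tibble with one row per replicate: `replicate`, `seed`, `count`,
#'   and `at_least_real` (did the replicate match or beat the real count?).
#' @method tidy motif_significance
#' @export
tidy.motif_significance <- function(x, ...) {
  tibble(replicate = seq_len(x$r),
         seed = x$seed + seq_len(x$r),
         count = x$random_counts,
         at_least_real = x$random_counts >= x$real_count)
}

#' One-row summary of a significance test
#'
#' @inheritParams tidy.motif_significance
#' @return a one-row tibble: model, r, seed, real_count, null mean/sd,
#'   p_value, z_score.
#' @method glance motif_significance
#' @export
glance.motif_significance <- function(x, ...) {
  tibble(model = x$model, r = x$r, seed = x$seed, real_count = x$real_count,
         null_mean = x$mean, null_sd = x$sd, p_value = x$p_value,
         z_score = x$z_score)
}

#' Plot the null distribution of a significance test
#'
#' Histogram of the per-replicate occurrence counts with the real count
#' marked by a vertical line.
#'
#' @param object a `motif_significance` object.
#' @param ... unused.
#' @return a ggplot object.
#' @method autoplot motif_significance
#' @export
autoplot.motif_significance <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$count)) +
    ggplot2::geom_histogram(bins = max(10, min(30, object$r)),
                            fill = "grey70", color = "grey30") +
    ggplot2::geom_vline(xintercept = object$real_count, color = "red",
                        linewidth = 1) +
    ggplot2::labs(
      x = "occurrences in null replicate", y = "replicates",
      title = sprintf("%s null, r = %d: real = %d, p = %.3g, z = %.3g",
                      object$model, object$r, object$real_count,
                      object$p_value, object$z_score)) +
    ggplot2::theme_minimal()
}
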