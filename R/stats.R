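#' Two-sample t test on a biomechanical measure
#'
#' Thin, defensively wrapped interface over the classical t statistics:
#' Welch (default, unequal variances), pooled-variance Student, or paired.
#' Two-sided throughout. When both groups have zero variance and equal
#' means the comparison is degenerate and `t = 0, p = 1` is returned (the
#' groups are indistinguishable).
#'
#' @param a,b Numeric vectors (length >= 2; paired mode requires equal
#'   lengths in matched specimen order).
#' @param mode `"welch"`, `"student"` or `"paired"`.
#' @return A list with `t_stat`, `p_value`, `df`, `n_a`, `n_b`.
#' @export
ttest_two_sample <- function(a, b, mode = c("welch", "student", "paired")) {
  mode <- match.arg(mode)
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) < 2L || length(b) < 2L) {
    abort_femurfe("Each group needs at least 2 observations.",
                  "femurfe_parameter_error")
  }
  if (mode == "paired" && length(a) != length(b)) {
    abort_femurfe("Paired mode requires equal group lengths.",
                  "femurfe_parameter_error")
  }
  degenerate <- if (mode == "paired") {
    stats::sd(a - b) == 0
  } else {
    stats::sd(a) == 0 && stats::sd(b) == 0
  }
  if (degenerate) {
    same <- if (mode == "paired") all(a == b) else mean(a) == mean(b)
    if (same) {
      return(list(t_stat = 0, p_value = 1, df = NA_real_,
                  n_a = length(a), n_b = length(b)))
    }
    return(list(t_stat = Inf * sign(mean(a) - mean(b)), p_value = 0,
                df = NA_real_, n_a = length(a), n_b = length(b)))
  }
  tt <- switch(mode,
    welch = stats::t.test(a, b, var.equal = FALSE),
    student = stats::t.test(a, b, var.equal = TRUE),
    paired = stats::t.test(a, b, paired = TRUE))
  list(t_stat = unname(tt$statistic), p_value = tt$p.value,
       df = unname(tt$parameter), n_a = length(a), n_b = length(b))
}

#' Build group-mean and comparison tables across segmentation methods
#'
#' Aggregates per-specimen FE summaries into (i) a per-method, per-side
#' table of group means of the four biomechanical measures and (ii) pairwise
#' comparisons of the full KI group against each narrowed variant, per side
#' and measure (3 pairs x 4 measures = 12 comparisons per side). Left and
#' right cohorts are never pooled.
#'
#' @param summaries Tibble of rows from [summarize_specimen()]; one row per
#'   (specimen, method), with every specimen carrying all requested methods.
#' @param alpha Significance level for flagging.
#' @param mode t-test mode passed to [ttest_two_sample()].
#' @param p_adjust Multiple-testing correction passed to
#'   [stats::p.adjust()]; default `"none"` (per-comparison reporting),
#'   `"holm"` available.
#' @param methods Method names, reference first.
#' @return An object of class `biomech_comparison`: list with `means`
#'   (tibble), `comparisons` (tibble), `alpha`, `mode`, `summaries`.
#' @export
build_tables <- function(summaries, alpha = 0.05,
                         mode = c("welch", "student", "paired"),
                         p_adjust = "none",
                         methods = c("KI", "KI-99.0", "KI-97.5", "KI-95.0")) {
  mode <- match.arg(mode)
  stopifnot(is.data.frame(summaries))
  measures <- c("mean_displacement", "mean_pressure", "mean_stress",
                "mean_strain")
  need <- c("specimen_id", "side", "method", measures)
  missing_cols <- setdiff(need, names(summaries))
  if (length(missing_cols)) {
    abort_femurfe(paste0("Missing columns: ",
                         paste(missing_cols, collapse = ", ")),
                  "femurfe_parameter_error")
  }
  summaries <- dplyr::filter(summaries, .data$method %in% methods)
  gaps <- summaries |>
    dplyr::count(.data$specimen_id, .data$side) |>
    dplyr::filter(.data$n != length(methods))
  if (nrow(gaps) > 0L) {
    abort_femurfe(
      paste0("Specimens missing method rows: ",
             paste(utils::head(gaps$specimen_id, 10), collapse = ", ")),
      "femurfe_missing_rows")
  }
  means <- summaries |>
    tidyr::pivot_longer(dplyr::all_of(measures), names_to = "measure",
                        values_to = "value") |>
    dplyr::mutate(measure = sub("^mean_", "", .data$measure)) |>
    dplyr::group_by(.data$side, .data$method, .data$measure) |>
    dplyr::summarise(mean = mean(.data$value), sd = stats::sd(.data$value),
                     n = dplyr::n(), .groups = "drop") |>
    dplyr::mutate(method = factor(.data$method, levels = methods)) |>
    dplyr::arrange(.data$side, .data$method)

  ref <- methods[1]
  variants <- methods[-1]
  comps <- list()
  for (sd_ in sort(unique(summaries$side))) {
    sub <- dplyr::filter(summaries, .data$side == sd_) |>
      dplyr::arrange(.data$specimen_id)
    ref_rows <- dplyr::filter(sub, .data$method == ref)
    for (vr in variants) {
      var_rows <- dplyr::filter(sub, .data$method == vr)
      for (ms in measures) {
        tt <- ttest_two_sample(ref_rows[[ms]], var_rows[[ms]], mode = mode)
        comps[[length(comps) + 1L]] <- tibble::tibble(
          side = sd_, measure = sub("^mean_", "", ms),
          method_a = ref, method_b = vr,
          n_a = tt$n_a, n_b = tt$n_b,
          t_stat = tt$t_stat, df = tt$df, p_value = tt$p_value)
      }
    }
  }
  comparisons <- dplyr::bind_rows(comps) |>
    dplyr::group_by(.data$side) |>
    dplyr::mutate(p_adj = stats::p.adjust(.data$p_value, method = p_adjust)) |>
    dplyr::ungroup() |>
    dplyr::mutate(significant = .data$p_adj < alpha)
  structure(list(means = means, comparisons = comparisons, alpha = alpha,
                 mode = mode, methods = methods, summaries = summaries),
            class = "biomech_comparison")
}

#' @exportS3Method base::print
print.biomech_comparison <- function(x, ...) {
  cat(sprintf(
    "<biomech_comparison> %d specimens x %d methods, %s t tests, alpha = %g\n",
    length(unique(x$summaries$specimen_id)), length(x$methods), x$mode,
    x$alpha))
  cat("\nGroup means:\n")
  print(x$means, n = Inf)
  cat("\nComparisons vs", x$methods[1], ":\n")
  print(x$comparisons, n = Inf)
  invisible(x)
}

#' Null-calibration of the group comparison machinery
#'
#' Simulates comparisons in which both groups are drawn from the same
#' distribution (the situation where all segmentation "methods" retain the
#' full intensity range, so no true effect exists) and returns the observed
#' fraction of p-values below `alpha`. For a calibrated test this fraction
#' estimates `alpha`.
#'
#' @param n_comparisons Number of simulated null comparisons.
#' @param n_per_group Specimens per group.
#' @param mean,sd Parameters of the common Gaussian the group values are
#'   drawn from (scale is irrelevant to calibration).
#' @param alpha Nominal level.
#' @param mode t-test mode.
#' @param seed Integer seed.
#' @return A list with `rejection_rate`, `n_comparisons`, `alpha` and the
#'   vector `p_values`.
#' @export
null_rejection_rate <- function(n_comparisons = 500L, n_per_group = 30L,
                                mean = 8, sd = 1, alpha = 0.05,
                                mode = "welch", seed = 1L) {
  p <- withr::with_seed(seed, {
    vapply(seq_len(n_comparisons), function(i) {
      a <- stats::rnorm(n_per_group, mean, sd)
      b <- stats::rnorm(n_per_group, mean, sd)
      ttest_two_sample(a, b, mode = mode)$p_value
    }, numeric(1))
  })
  list(rejection_rate = mean(p < alpha), n_comparisons = n_comparisons,
       alpha = alpha, p_values = p)
}
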