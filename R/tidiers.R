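# broom-style tidiers for the package's fitted/summary objects.

#' @describeIn fit_hill One-row tibble of the fitted Hill parameters.
#' @param x A `hill_fit`.
#' @param ... Unused.
#' @method tidy hill_fit
#' @export
tidy.hill_fit <- function(x, ...) {
  tibble::tibble(
    bottom = x$bottom, top = x$top, ec50 = x$ec50, hill = x$hill,
    direction = x$direction, rss = x$rss, converged = x$converged, n = x$n
  )
}

#' @describeIn fm_index Tidy one-row summary of an FM comparison.
#' @param x An `fm_result`.
#' @param ... Unused.
#' @method tidy fm_result
#' @export
tidy.fm_result <- function(x, ...) {
  tibble::tibble(
    fm_index = x$B, Tk = x$Tk, Pk = x$Pk, Qk = x$Qk, n = x$n,
    expected_B = x$expected_B, z = x$z, p_value = x$p_value,
    null_mode = x$null_mode, n_permutations = x$n_permutations
  )
}

#' @describeIn fm_index Alias of `tidy()` for an `fm_result`.
#' @method glance fm_result
#' @export
glance.fm_result <- function(x, ...) tidy.fm_result(x, ...)

#' @describeIn repeated_cv_classify Aggregated confusion matrix in long form
#'   (`true`, `predicted`, `n`).
#' @param x A `cv_classification`.
#' @param ... Unused.
#' @method tidy cv_classification
#' @export
tidy.cv_classification <- function(x, ...) {
  as.data.frame(as.table(x$confusion), responseName = "n") %>%
    tibble::as_tibble() %>%
    dplyr::mutate(true = as.character(.data$true),
                  predicted = as.character(.data$predicted))
}

#' @describeIn repeated_cv_classify One-row accuracy summary.
#' @method glance cv_classification
#' @export
glance.cv_classification <- function(x, ...) {
  tibble::tibble(
    accuracy = x$accuracy,
    accuracy_sd = stats::sd(x$per_repeat_accuracy),
    folds = x$scheme$folds, repeats = x$scheme$repeats, ntree = x$ntree
  )
}

#' @describeIn permutation_baseline One-row summary of the permutation null.
#' @param x A `cv_permutation`.
#' @param ... Unused.
#' @method glance cv_permutation
#' @export
glance.cv_permutation <- function(x, ...) {
  tibble::tibble(
    observed = x$observed,
    null_mean = mean(x$null_accuracy),
    null_q95 = unname(stats::quantile(x$null_accuracy, 0.95)),
    p_value = x$p_value,
    n_label_perms = x$n_label_perms
  )
}

#' @describeIn conservatism_comparison Per-chemical log10 NAM/in-vivo ratios.
#' @param x A `conservatism_result`.
#' @param ... Unused.
#' @method tidy conservatism_result
#' @export
tidy.conservatism_result <- function(x, ...) x$ratios

#' @describeIn conservatism_comparison One-row conservatism summary.
#' @method glance conservatism_result
#' @export
glance.conservatism_result <- function(x, ...) {
  tibble::tibble(
    n = x$n,
    frac_unconservative = x$frac_unconservative,
    frac_unconservative_within_10x = x$frac_unconservative_within_10x
  )
}
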