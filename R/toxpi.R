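#' Scale a POD table into 0-1 ToxPi component scores
#'
#' Inversely scales the PODs of each phenotype across chemicals onto [0, 1]:
#' the lowest POD (highest bioactivity) maps to 1, the highest POD maps to 0,
#' and intermediate values interpolate linearly -- on the log10 concentration
#' scale by default, since the tested concentrations are log-spaced. PODs
#' censored at the maximum tested concentration score exactly 0 (no observed
#' bioactivity); PODs censored low enter at their bound. Phenotypes with
#' fewer than two distinct finite POD values cannot be scaled and are scored
#' all-0 with a warning.
#'
#' @param pods A [fit_pod_table()] result (or any tibble with `chemical`,
#'   `cell_type`, `phenotype`, `pod`, `censored`, `censor_side`).
#' @param scale_mode `"log10"` (default) or `"linear"` interpolation scale.
#' @return A tibble of class `toxpi_input`: `chemical`, `slice` (the cell
#'   type), `phenotype`, `score` in [0, 1]. Degenerate phenotypes are listed
#'   in the `flagged_phenotypes` attribute.
#' @export
scale_pod_matrix <- function(pods, scale_mode = c("log10", "linear")) {
  scale_mode <- match.arg(scale_mode)
  assert_columns(pods, c("chemical", "cell_type", "phenotype", "pod", "censored"),
                 "POD table")
  if (!"censor_side" %in% names(pods)) {
    pods$censor_side <- ifelse(pods$censored, "high", NA_character_)
  }

  flagged <- character(0)
  out <- pods %>%
    dplyr::group_by(.data$cell_type, .data$phenotype) %>%
    dplyr::group_modify(function(df, key) {
      # high-censored PODs score 0 by definition; scaling anchors come from
      # the remaining (observed or low-censored) values
      observed <- !(df$censored & df$censor_side == "high")
      x <- if (scale_mode == "log10") log10(df$pod) else df$pod
      xo <- x[observed]
      score <- rep(0, nrow(df))
      if (length(unique(xo)) >= 2) {
        rng <- range(xo)
        score[observed] <- (rng[2] - xo) / (rng[2] - rng[1])
      } else {
        flagged <<- c(flagged, key$phenotype)
      }
      tibble::tibble(chemical = df$chemical, score = score)
    }) %>%
    dplyr::ungroup() %>%
    dplyr::transmute(
      chemical = .data$chemical, slice = .data$cell_type,
      phenotype = .data$phenotype, score = .data$score
    )

  if (length(flagged) > 0) {
    warn(sprintf(
      "%d phenotype(s) had < 2 distinct POD values and were scored all-0: %s",
      length(flagged),
      paste(utils::head(flagged, 3), collapse = ", ")
    ))
  }
  structure(out, class = c("toxpi_input", class(out)),
            flagged_phenotypes = flagged, scale_mode = scale_mode)
}

#' Aggregate component scores into ToxPi slice and overall scores
#'
#' Each slice (cell type) score is the arithmetic mean of its member
#' phenotype scores; the overall ToxPi score is the weighted mean of slice
#' scores (equal weights by default, one slice per cell type). Chemicals are
#' ranked by descending overall score, ties broken lexicographically by
#' chemical id so the ranking is reproducible.
#'
#' @param scores A [scale_pod_matrix()] result.
#' @param weights Optional named numeric vector of slice weights (must cover
#'   every slice and sum to 1). Default: equal.
#' @return A tibble of class `toxpi_profiles`, one row per chemical x slice:
#'   `chemical`, `slice`, `slice_score`, `overall_score`, `rank`.
#' @export
toxpi_profile <- function(scores, weights = NULL) {
  assert_columns(scores, c("chemical", "slice", "phenotype", "score"),
                 "ToxPi input")
  slices <- sort(unique(scores$slice))
  counts <- scores %>% dplyr::count(.data$slice)
  if (any(counts$n == 0) || length(slices) == 0) {
    stop_toxscreen("every slice needs at least one phenotype",
                   "toxscreen_config_error")
  }
  if (is.null(weights)) {
    weights <- setNames(rep(1 / length(slices), length(slices)), slices)
  }
  if (!setequal(names(weights), slices) || abs(sum(weights) - 1) > 1e-8) {
    stop_toxscreen("weights must name every slice and sum to 1",
                   "toxscreen_config_error")
  }

  slice_scores <- scores %>%
    dplyr::group_by(.data$chemical, .data$slice) %>%
    dplyr::summarise(slice_score = mean(.data$score), .groups = "drop")

  overall <- slice_scores %>%
    dplyr::mutate(w = unname(weights[.data$slice])) %>%
    dplyr::group_by(.data$chemical) %>%
    dplyr::summarise(overall_score = sum(.data$w * .data$slice_score),
                     .groups = "drop") %>%
    dplyr::arrange(dplyr::desc(.data$overall_score), .data$chemical) %>%
    dplyr::mutate(rank = dplyr::row_number())

  out <- slice_scores %>%
    dplyr::left_join(overall, by = "chemical") %>%
    dplyr::arrange(.data$rank, .data$slice)
  structure(out, class = c("toxpi_profiles", class(out)), weights = weights)
}

#' Summarize ToxPi score ranges by chemical class
#'
#' Computes the minimum, median and maximum slice score per chemical class
#' and cell type, and the same summaries for the overall score, then ranks
#' classes by their median overall score (most bioactive first).
#'
#' @param profiles A [toxpi_profile()] result.
#' @param classing Data frame with `chemical` and `class` covering every
#'   chemical in `profiles`.
#' @return A tibble: `class`, `slice` (cell types plus `"overall"`), `min`,
#'   `median`, `max`, `n_chemicals`, and `class_rank` (by median overall).
#' @export
class_score_ranges <- function(profiles, classing) {
  assert_columns(classing, c("chemical", "class"), "classing table")
  unknown <- setdiff(unique(profiles$chemical), classing$chemical)
  if (length(unknown) > 0) {
    stop_toxscreen(
      paste("chemical(s) without a class label:",
            paste(utils::head(unknown, 5), collapse = ", ")),
      "toxscreen_input_error"
    )
  }
  joined <- dplyr::left_join(profiles, classing[, c("chemical", "class")],
                             by = "chemical")

  per_slice <- joined %>%
    dplyr::group_by(.data$class, .data$slice) %>%
    dplyr::summarise(
      min = min(.data$slice_score), median = stats::median(.data$slice_score),
      max = max(.data$slice_score),
      n_chemicals = dplyr::n_distinct(.data$chemical), .groups = "drop"
    )
  per_overall <- joined %>%
    dplyr::distinct(.data$chemical, .data$class, .data$overall_score) %>%
    dplyr::group_by(.data$class) %>%
    dplyr::summarise(
      slice = "overall",
      min = min(.data$overall_score), median = stats::median(.data$overall_score),
      max = max(.data$overall_score),
      n_chemicals = dplyr::n(), .groups = "drop"
    )
  rank_tbl <- per_overall %>%
    dplyr::arrange(dplyr::desc(.data$median), .data$class) %>%
    dplyr::mutate(class_rank = dplyr::row_number()) %>%
    dplyr::select("class", "class_rank")

  dplyr::bind_rows(per_slice, per_overall) %>%
    dplyr::left_join(rank_tbl, by = "class") %>%
    dplyr::arrange(.data$class_rank, .data$slice)
}
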