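#' Five-parameter assay quality-control report
#'
#' Evaluates each plate x phenotype against the five plate-quality
#' parameters used for cell-based screening assays:
#' \enumerate{
#'   \item variance (as CV%) in replicate wells for each of two negative
#'     controls (vehicle and medium-only wells);
#'   \item the difference between the two negative controls (Welch t-test);
#'   \item intra-plate replicate correlation (mean Pearson correlation
#'     between treated replicate vectors on the same plate);
#'   \item inter-plate replicate correlation (correlation of per-condition
#'     mean responses between plates sharing a phenotype);
#'   \item EC50 of the positive control inside its expected window.
#' }
#' Checks whose data are absent (e.g. no medium wells, a single plate per
#' phenotype, no positive-control expectations) are reported as
#' not-evaluable (`pass = NA`), never silently passed.
#'
#' @param measurements Well table (raw or normalized scale), as produced by
#'   [simulate_screen()]`$measurements` or [load_screen_table()].
#' @param positive_controls Optional tibble with columns `chemical`,
#'   `phenotype`, `ec50_min`, `ec50_max` (uM) giving the expected EC50 window
#'   of the positive-control chemical for that phenotype.
#' @param thresholds Named list: `cv_max` (negative-control CV%, default 15),
#'   `diff_alpha` (significance level for the control-difference check,
#'   default 0.05; the check passes when the controls do NOT differ),
#'   `cor_min` (replicate-correlation floor, default 0.8).
#' @param vehicle_id,medium_id Chemical ids of the two negative controls.
#' @return A tibble of class `qc_report`: `plate`, `phenotype`, `parameter`
#'   (`"negcontrol_cv_vehicle"`, `"negcontrol_cv_medium"`,
#'   `"vehicle_vs_medium"`, `"intra_plate_cor"`, `"inter_plate_cor"`,
#'   `"positive_control_ec50"`), `value`, `pass` (logical; `NA` =
#'   not-evaluable).
#' @export
qc_assay <- function(measurements,
                     positive_controls = NULL,
                     thresholds = list(),
                     vehicle_id = "vehicle_control",
                     medium_id = "medium_control") {
  thr <- utils::modifyList(
    list(cv_max = 15, diff_alpha = 0.05, cor_min = 0.8), thresholds
  )
  measurements <- tibble::as_tibble(measurements)
  assert_columns(
    measurements,
    c("chemical", "phenotype", "plate", "conc_uM", "replicate", "response_pct"),
    "measurement table"
  )
  groups <- measurements %>% dplyr::distinct(.data$plate, .data$phenotype)

  report <- purrr::pmap_dfr(groups, function(plate, phenotype) {
    m <- measurements[measurements$plate == plate &
                        measurements$phenotype == phenotype, ]
    veh <- m$response_pct[m$chemical == vehicle_id & m$conc_uM == 0]
    med <- m$response_pct[m$chemical == medium_id & m$conc_uM == 0]

    cv <- function(x) {
      if (length(x) < 2 || mean(x) == 0) NA_real_ else 100 * stats::sd(x) / mean(x)
    }
    cv_veh <- cv(veh)
    cv_med <- cv(med)

    diff_p <- if (length(veh) >= 2 && length(med) >= 2 &&
                    (stats::sd(veh) > 0 || stats::sd(med) > 0)) {
      stats::t.test(veh, med)$p.value
    } else NA_real_

    # intra-plate: mean pairwise correlation between replicate vectors over
    # treated chemical x concentration conditions
    treated <- m %>%
      dplyr::filter(!(.data$chemical %in% c(vehicle_id, medium_id)),
                    .data$conc_uM > 0)
    intra <- NA_real_
    reps <- sort(unique(treated$replicate))
    if (length(reps) >= 2 && nrow(treated) > 0) {
      wide <- treated %>%
        dplyr::select("chemical", "conc_uM", "replicate", "response_pct") %>%
        tidyr::pivot_wider(names_from = "replicate",
                           values_from = "response_pct")
      mat <- as.matrix(wide[, as.character(reps), drop = FALSE])
      mat <- mat[stats::complete.cases(mat), , drop = FALSE]
      if (nrow(mat) >= 3 && all(apply(mat, 2, stats::sd) > 0)) {
        cm <- stats::cor(mat)
        intra <- mean(cm[upper.tri(cm)])
      }
    }

    tibble::tibble(
      plate = plate, phenotype = phenotype,
      parameter = c("negcontrol_cv_vehicle", "negcontrol_cv_medium",
                    "vehicle_vs_medium", "intra_plate_cor"),
      value = c(cv_veh, cv_med, diff_p, intra),
      pass = c(
        if (is.na(cv_veh)) NA else cv_veh <= thr$cv_max,
        if (is.na(cv_med)) NA else cv_med <= thr$cv_max,
        if (is.na(diff_p)) NA else diff_p >= thr$diff_alpha,
        if (is.na(intra)) NA else intra >= thr$cor_min
      )
    )
  })

  # inter-plate correlation: per-condition means compared across the plates
  # sharing a phenotype
  inter <- measurements %>%
    dplyr::filter(!(.data$chemical %in% c(vehicle_id, medium_id)),
                  .data$conc_uM > 0) %>%
    dplyr::group_by(.data$phenotype) %>%
    dplyr::group_modify(function(df, key) {
      plates <- unique(df$plate)
      if (length(plates) < 2) {
        return(tibble::tibble(plate = plates[1], value = NA_real_))
      }
      wide <- df %>%
        dplyr::group_by(.data$plate, .data$chemical, .data$conc_uM) %>%
        dplyr::summarise(mu = mean(.data$response_pct), .groups = "drop") %>%
        tidyr::pivot_wider(names_from = "plate", values_from = "mu")
      mat <- as.matrix(wide[, plates, drop = FALSE])
      mat <- mat[stats::complete.cases(mat), , drop = FALSE]
      val <- if (nrow(mat) >= 3 && all(apply(mat, 2, stats::sd) > 0)) {
        cm <- stats::cor(mat)
        mean(cm[upper.tri(cm)])
      } else NA_real_
      tibble::tibble(plate = paste(plates, collapse = "|"), value = val)
    }) %>%
    dplyr::ungroup() %>%
    dplyr::mutate(
      parameter = "inter_plate_cor",
      pass = ifelse(is.na(.data$value), NA, .data$value >= thr$cor_min)
    ) %>%
    dplyr::select("plate", "phenotype", "parameter", "value", "pass")

  # positive-control EC50 window
  pos <- if (!is.null(positive_controls) && nrow(positive_controls) > 0) {
    assert_columns(positive_controls,
                   c("chemical", "phenotype", "ec50_min", "ec50_max"),
                   "positive-control table")
    purrr::pmap_dfr(positive_controls, function(chemical, phenotype,
                                                ec50_min, ec50_max, ...) {
      m <- measurements[measurements$chemical == chemical &
                          measurements$phenotype == phenotype &
                          measurements$conc_uM > 0, ]
      if (nrow(m) == 0 || length(unique(m$conc_uM)) < 4) {
        return(tibble::tibble(
          plate = NA_character_, phenotype = phenotype,
          parameter = "positive_control_ec50", value = NA_real_, pass = NA
        ))
      }
      fit <- fit_hill(m$conc_uM, m$response_pct)
      ok <- fit$converged && !is.na(fit$ec50) &&
        fit$ec50 >= ec50_min && fit$ec50 <= ec50_max
      tibble::tibble(
        plate = m$plate[1], phenotype = phenotype,
        parameter = "positive_control_ec50",
        value = if (fit$converged) fit$ec50 else NA_real_,
        pass = ok
      )
    })
  } else {
    groups %>%
      dplyr::mutate(parameter = "positive_control_ec50",
                    value = NA_real_, pass = NA)
  }

  out <- dplyr::bind_rows(report, inter, pos) %>%
    dplyr::arrange(.data$phenotype, .data$parameter)
  structure(out, class = c("qc_report", class(out)), thresholds = thr)
}

#' Contrast functional vs cytotoxicity POD distributions
#'
#' Tests, per cell type and pooled over all cell types, whether functional
#' phenotypes have lower PODs (are more sensitive) than cytotoxicity
#' phenotypes, by a one-sided Wilcoxon rank-sum test on log10 POD. Censored
#' PODs enter at their censoring bound, which is conservative for this
#' contrast (both categories are pushed toward the bound).
#'
#' @param pods A [fit_pod_table()] result.
#' @return A tibble with one row per cell type plus `"all"`: `cell_type`,
#'   `n_functional`, `n_cytotoxicity`, `statistic` (rank-sum W), `p_value`
#'   (one-sided, functional < cytotoxicity), `evaluable`, `low_n` (fewer
#'   than 2 PODs in either category).
#' @export
phenotype_category_contrast <- function(pods) {
  assert_columns(pods, c("cell_type", "category", "pod"), "POD table")
  scopes <- c(unique(pods$cell_type), "all")
  purrr::map_dfr(scopes, function(ct) {
    df <- if (ct == "all") pods else pods[pods$cell_type == ct, ]
    f <- log10(df$pod[df$category == "functional"])
    c_ <- log10(df$pod[df$category == "cytotoxicity"])
    if (length(f) == 0 || length(c_) == 0) {
      return(tibble::tibble(
        cell_type = ct, n_functional = length(f), n_cytotoxicity = length(c_),
        statistic = NA_real_, p_value = NA_real_,
        evaluable = FALSE, low_n = TRUE
      ))
    }
    wt <- suppressWarnings(
      stats::wilcox.test(f, c_, alternative = "less", exact = FALSE)
    )
    tibble::tibble(
      cell_type = ct, n_functional = length(f), n_cytotoxicity = length(c_),
      statistic = unname(wt$statistic), p_value = wt$p.value,
      evaluable = TRUE, low_n = length(f) < 2 || length(c_) < 2
    )
  })
}
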