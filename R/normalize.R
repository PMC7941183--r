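#' Normalize well responses to plate-matched vehicle controls
#'
#' Rescales every well so that the mean of the vehicle-control wells on the
#' same plate for the same phenotype maps to 100% of control, and records the
#' vehicle mean and standard deviation per plate and phenotype. The vehicle
#' standard deviation (on the normalized scale) defines the
#' one-standard-deviation benchmark response used for POD derivation.
#'
#' @param measurements Data frame of wells with columns `chemical`,
#'   `cell_type`, `phenotype`, `plate`, `conc_uM`, `replicate`,
#'   `response_pct` (raw or already %-of-control values; the function is a
#'   ratio, so both work). Vehicle wells are rows with
#'   `chemical == vehicle_id` and `conc_uM == 0`.
#' @param vehicle_id Chemical id marking vehicle-control wells.
#' @return A list of class `normalized_screen` with `measurements` (the input
#'   with `response_pct` rescaled) and `vehicle_stats` (one row per plate x
#'   phenotype: `mean_pct` = 100, `sd_pct`, `n_wells`).
#' @export
normalize_to_vehicle <- function(measurements, vehicle_id = "vehicle_control") {
  measurements <- tibble::as_tibble(measurements)
  assert_columns(
    measurements,
    c("chemical", "cell_type", "phenotype", "plate", "conc_uM", "replicate",
      "response_pct"),
    "measurement table"
  )
  veh <- measurements %>%
    dplyr::filter(.data$chemical == vehicle_id, .data$conc_uM == 0)

  stats_raw <- veh %>%
    dplyr::group_by(.data$plate, .data$phenotype) %>%
    dplyr::summarise(
      raw_mean = mean(.data$response_pct),
      raw_sd = stats::sd(.data$response_pct),
      n_wells = dplyr::n(),
      .groups = "drop"
    )

  need <- measurements %>% dplyr::distinct(.data$plate, .data$phenotype)
  missing <- dplyr::anti_join(need, stats_raw, by = c("plate", "phenotype"))
  short <- stats_raw %>% dplyr::filter(.data$n_wells < 2)
  if (nrow(missing) > 0 || nrow(short) > 0) {
    bad <- dplyr::bind_rows(missing[, c("plate", "phenotype")],
                            short[, c("plate", "phenotype")])
    stop_toxscreen(
      paste0(
        "need >= 2 vehicle wells per plate/phenotype; missing or short for: ",
        paste(utils::head(paste(bad$plate, bad$phenotype, sep = "/"), 5),
              collapse = ", "),
        if (nrow(bad) > 5) sprintf(" (+%d more)", nrow(bad) - 5) else ""
      ),
      "toxscreen_qc_error"
    )
  }
  if (any(stats_raw$raw_mean == 0)) {
    stop_toxscreen("vehicle mean of 0 cannot anchor normalization",
                   "toxscreen_degenerate_error")
  }

  normalized <- measurements %>%
    dplyr::left_join(stats_raw, by = c("plate", "phenotype")) %>%
    dplyr::mutate(response_pct = 100 * .data$response_pct / .data$raw_mean) %>%
    dplyr::select(-"raw_mean", -"raw_sd", -"n_wells")

  vehicle_stats <- stats_raw %>%
    dplyr::transmute(
      plate = .data$plate, phenotype = .data$phenotype,
      mean_pct = 100,
      sd_pct = 100 * .data$raw_sd / .data$raw_mean,
      n_wells = .data$n_wells
    )

  structure(
    list(measurements = normalized, vehicle_stats = vehicle_stats),
    class = "normalized_screen"
  )
}
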