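#' Hill (four-parameter logistic) concentration-response function
#'
#' `response = bottom + (top - bottom) / (1 + (ec50 / conc)^hill)`, so the
#' response tends to `bottom` as concentration approaches 0 and to `top` at
#' high concentration; at `conc = ec50` it is the midpoint.
#'
#' @param conc Concentration(s), uM; must be > 0 (use the vehicle mean for 0).
#' @param bottom,top Response asymptotes in percent of vehicle control.
#' @param ec50 Half-maximal concentration, uM (> 0).
#' @param hill Hill slope (> 0).
#' @return Numeric vector of responses (% of control).
#' @export
hill_response <- function(conc, bottom, top, ec50, hill) {
  bottom + (top - bottom) / (1 + (ec50 / conc)^hill)
}

#' Closed-form point of departure of a known Hill curve
#'
#' Inverts the Hill function analytically to find the lowest concentration at
#' which the curve departs from the vehicle baseline (100% of control) by
#' `vehicle_sd` percent -- the one-standard-deviation benchmark response.
#' This is the exact ground-truth POD for a simulated curve, used as the
#' independent oracle for the numerical POD derivation in the
#' concentration-response module.
#'
#' Solving `|f(c) - 100| = vehicle_sd` with `f` anchored at `bottom = 100`
#' gives `c = ec50 / ((|top - 100| - vehicle_sd) / vehicle_sd)^(1/hill)`.
#' When the asymptotic effect `|top - 100|` does not exceed `vehicle_sd` the
#' curve never crosses the benchmark and the POD is censored (`Inf`).
#'
#' @param top Asymptotic response (% of control); `bottom` is fixed at 100.
#' @param ec50 EC50 in uM (> 0). `NA` is treated as inactive.
#' @param hill Hill slope (> 0).
#' @param vehicle_sd Vehicle-control standard deviation (% of control, > 0).
#' @param active Logical; inactive curves are flat at 100 and always censored.
#' @return POD in uM; `Inf` when the benchmark is never reached. Vectorized.
#' @export
#' @examples
#' analytic_pod(top = 40, ec50 = 1, hill = 1, vehicle_sd = 5) # 1/11
analytic_pod <- function(top, ec50, hill, vehicle_sd, active = TRUE) {
  if (!is_scalar_number(vehicle_sd) || vehicle_sd <= 0) {
    stop_toxscreen("vehicle_sd must be a positive number", "toxscreen_input_error")
  }
  n <- max(length(top), length(ec50), length(hill), length(active))
  top <- rep_len(top, n); ec50 <- rep_len(ec50, n)
  hill <- rep_len(hill, n); active <- rep_len(active, n)
  live <- active & !is.na(ec50)
  if (any(ec50[live] <= 0, na.rm = TRUE) || any(hill[live] <= 0, na.rm = TRUE)) {
    stop_toxscreen("ec50 and hill must be positive for active curves",
                   "toxscreen_input_error")
  }
  effect <- abs(top - 100)
  pod <- rep(Inf, n)
  ok <- live & effect > vehicle_sd
  pod[ok] <- ec50[ok] / ((effect[ok] - vehicle_sd) / vehicle_sd)^(1 / hill[ok])
  pod
}

# Draw the true curve parameters for every chemical x phenotype.
simulate_truth <- function(design, profiles, seed) {
  chems <- design$chemicals
  phenos <- design$phenotypes
  purrr::map_dfr(seq_len(nrow(chems)), function(i) {
    chem <- chems$chemical[i]
    cls <- chems$class[i]
    set.seed(derive_seed(seed, c(1L, i)))
    # chemical-level potency shift shared across cell types: members of a
    # class differ in overall potency but keep the class's cell-type pattern
    chem_shift <- stats::rnorm(1, 0, 0.15)
    purrr::map_dfr(design$cell_types, function(ct) {
      prof <- profiles[profiles$class == cls & profiles$cell_type == ct, ]
      ph <- phenos[phenos$cell_type == ct, ]
      m <- nrow(ph)
      act <- stats::runif(m) < prof$activity_prob
      lec50 <- prof$mean_log10_ec50 + chem_shift +
        stats::rnorm(m, 0, prof$sd_log10_ec50)
      dirs <- ifelse(stats::runif(m) < prof$direction_prob, "decreasing", "increasing")
      eff <- stats::runif(m, 35, 65)
      top <- ifelse(dirs == "decreasing", 100 - eff, 100 + eff)
      hill <- stats::runif(m, 0.8, 3)
      tibble::tibble(
        chemical = chem, class = cls, cell_type = ct,
        phenotype = ph$phenotype, category = ph$category,
        active = act,
        bottom = 100,
        top = ifelse(act, top, 100),
        ec50 = ifelse(act, 10^lec50, NA_real_),
        hill = ifelse(act, hill, NA_real_),
        direction = ifelse(act, dirs, "none")
      )
    })
  })
}

#' Simulate a multi-cell-type concentration-response screen
#'
#' Generates plate-level well measurements with the statistical structure the
#' downstream analysis assumes -- monotone Hill-shaped responses anchored at
#' the vehicle baseline, class- and cell-type-specific potency, and
#' independent Gaussian well noise -- together with the ground-truth curve
#' parameters for every chemical x phenotype, so each pipeline stage can be
#' validated against known truth.
#'
#' One plate is simulated per cell type. Treated wells get
#' `hill_response(conc) + N(0, noise_sd)`; vehicle and medium negative-control
#' wells are drawn from `N(100, noise_sd)` at concentration 0. Substreams are
#' derived from the master seed per chemical and per plate, so the same seed
#' reproduces the screen bit for bit.
#'
#' @param profiles Class-by-cell-type potency profiles
#'   (see [class_potency_profiles()]).
#' @param design A [screen_design()].
#' @param noise_sd Gaussian well noise, percent of control (>= 0).
#' @param seed Master integer seed.
#' @return An object of class `synthetic_screen`: a list with `measurements`
#'   (one row per well: `chemical`, `class`, `cell_type`, `phenotype`,
#'   `category`, `plate`, `conc_uM`, `replicate`, `response_pct`), `truth`
#'   (true curve parameters), plus `design`, `noise_sd`, `seed`.
#' @export
#' @examples
#' scr <- simulate_screen(seed = 7)
#' dplyr::count(scr$measurements, cell_type)
simulate_screen <- function(profiles = class_potency_profiles(),
                            design = screen_design(),
                            noise_sd = 10,
                            seed = 1L) {
  if (!inherits(design, "screen_design")) {
    stop_toxscreen("design must be a screen_design object", "toxscreen_config_error")
  }
  if (!is_scalar_number(noise_sd) || noise_sd < 0) {
    stop_toxscreen("noise_sd must be a non-negative number", "toxscreen_input_error")
  }
  validate_profiles(profiles, design)
  n_class <- table(design$chemicals$class)
  if (any(n_class < 1)) {
    stop_toxscreen("every class needs at least one chemical", "toxscreen_config_error")
  }

  truth <- simulate_truth(design, profiles, seed)

  # treated wells
  conc <- design$conc_uM
  reps <- seq_len(design$n_replicates)
  treated <- truth %>%
    tidyr::expand_grid(conc_uM = conc, replicate = reps) %>%
    dplyr::mutate(
      plate = paste0("plate_", .data$cell_type),
      mu = ifelse(
        .data$active,
        hill_response(.data$conc_uM, .data$bottom, .data$top, .data$ec50, .data$hill),
        100
      )
    )
  set.seed(derive_seed(seed, 2L))
  treated$response_pct <- treated$mu + stats::rnorm(nrow(treated), 0, noise_sd)

  # negative-control wells (vehicle + optional medium), per plate x phenotype
  controls <- design$phenotypes %>%
    tidyr::expand_grid(
      tibble::tibble(
        chemical = c(
          rep("vehicle_control", design$n_vehicle_wells),
          rep("medium_control", design$n_medium_wells)
        ),
        replicate = c(
          seq_len(design$n_vehicle_wells),
          seq_len(design$n_medium_wells)
        )
      )
    ) %>%
    dplyr::mutate(
      class = NA_character_,
      plate = paste0("plate_", .data$cell_type),
      conc_uM = 0
    )
  set.seed(derive_seed(seed, 3L))
  controls$response_pct <- stats::rnorm(nrow(controls), 100, noise_sd)

  cols <- c("chemical", "class", "cell_type", "phenotype", "category",
            "plate", "conc_uM", "replicate", "response_pct")
  measurements <- dplyr::bind_rows(
    dplyr::select(treated, dplyr::all_of(cols)),
    dplyr::select(controls, dplyr::all_of(cols))
  ) %>%
    dplyr::arrange(.data$cell_type, .data$phenotype, .data$chemical,
                   dplyr::desc(.data$conc_uM), .data$replicate)

  structure(
    list(
      design = design,
      measurements = measurements,
      truth = truth,
      noise_sd = noise_sd,
      seed = as.integer(seed)
    ),
    class = "synthetic_screen"
  )
}

#' @export
print.synthetic_screen <- function(x, ...) {
  cat("<synthetic_screen>\n")
  cat("  wells:", nrow(x$measurements), "| curves:", nrow(x$truth),
      "| noise_sd:", x$noise_sd, "% | seed:", x$seed, "\n")
  print(x$design)
  invisible(x)
}
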