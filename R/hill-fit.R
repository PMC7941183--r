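#' Fit a Hill concentration-response model to one chemical x phenotype
#'
#' Bounded least-squares fit of
#' `response = bottom + (top - bottom) / (1 + (ec50/conc)^hill)` to all
#' replicate points (no pre-averaging), parameterized in log10(EC50).
#' Three starts seed the EC50 at the minimum, median and maximum tested
#' concentration; the converged start with the lowest residual sum of squares
#' wins. Fit bounds: EC50 in [1e-4, 1e4] uM, hill slope in [0.3, 8].
#'
#' @param conc Concentrations in uM (> 0); replicate points repeat values.
#' @param response Responses in % of vehicle control.
#' @param ec50_bounds,hill_bounds Length-2 numeric bounds for EC50 (uM) and
#'   the Hill slope.
#' @return An object of class `hill_fit`: `bottom`, `top`, `ec50`, `hill`,
#'   `direction` (`"increasing"`, `"decreasing"` or `"flat"`), `rss`,
#'   `converged`, `n`, and the fitted points (`data`).
#' @export
#' @examples
#' conc <- rep(c(100, 10, 1, 0.1, 0.01), each = 3)
#' fit_hill(conc, hill_response(conc, 100, 40, 1, 1))
fit_hill <- function(conc, response,
                     ec50_bounds = c(1e-4, 1e4),
                     hill_bounds = c(0.3, 8)) {
  keep <- is.finite(conc) & is.finite(response) & conc > 0
  conc <- conc[keep]; response <- response[keep]
  if (length(unique(conc)) < 4) {
    stop_toxscreen("Hill fit needs >= 4 distinct concentrations",
                   "toxscreen_insufficient_data_error")
  }
  lc <- log10(conc)
  rng <- range(response)
  lower <- c(bottom = rng[1] - 50, top = rng[1] - 50,
             lec50 = log10(ec50_bounds[1]), hill = hill_bounds[1])
  upper <- c(bottom = rng[2] + 50, top = rng[2] + 50,
             lec50 = log10(ec50_bounds[2]), hill = hill_bounds[2])
  extreme <- response[which.max(abs(response - 100))]
  starts <- lapply(c(min(lc), stats::median(lc), max(lc)), function(s) {
    list(bottom = 100, top = extreme, lec50 = s, hill = 1)
  })

  best <- NULL
  for (st in starts) {
    fit <- tryCatch(
      minpack.lm::nlsLM(
        response ~ bottom + (top - bottom) / (1 + 10^((lec50 - lc) * hill)),
        start = st, lower = lower, upper = upper,
        control = minpack.lm::nls.lm.control(maxiter = 200)
      ),
      error = function(e) NULL
    )
    if (is.null(fit)) next
    rss <- sum(stats::residuals(fit)^2)
    if (is.null(best) || rss < best$rss) best <- list(fit = fit, rss = rss)
  }

  pts <- tibble::tibble(conc_uM = conc, response_pct = response)
  rss_flat <- sum((response - mean(response))^2)
  if (is.null(best)) {
    # optimizer failed on every start: flat placeholder, flagged; derive_pod
    # falls back to nonparametric interpolation of the stored points
    mu <- mean(response)
    return(structure(
      list(bottom = mu, top = mu, ec50 = NA_real_, hill = NA_real_,
           direction = "flat", rss = sum((response - mu)^2),
           rss_flat = rss_flat, f_pvalue = 1,
           converged = FALSE, n = length(response), data = pts),
      class = "hill_fit"
    ))
  }

  cf <- stats::coef(best$fit)
  direction <- if (abs(cf[["top"]] - cf[["bottom"]]) < 1e-8) {
    "flat"
  } else if (cf[["top"]] > cf[["bottom"]]) "increasing" else "decreasing"
  # F-test of the Hill model against a flat (intercept-only) model: the
  # evidence that the response depends on concentration at all. Used by
  # fit_pod_table() as the activity call that gates POD derivation.
  n_pts <- length(response)
  f_p <- if (best$rss <= .Machine$double.eps * max(1, rss_flat)) {
    if (rss_flat <= .Machine$double.eps) 1 else 0
  } else if (rss_flat <= best$rss || n_pts <= 4) {
    1
  } else {
    f <- ((rss_flat - best$rss) / 3) / (best$rss / (n_pts - 4))
    stats::pf(f, 3, n_pts - 4, lower.tail = FALSE)
  }
  structure(
    list(
      bottom = unname(cf[["bottom"]]), top = unname(cf[["top"]]),
      ec50 = 10^unname(cf[["lec50"]]), hill = unname(cf[["hill"]]),
      direction = direction, rss = best$rss, rss_flat = rss_flat,
      f_pvalue = f_p, converged = TRUE,
      n = length(response), data = pts
    ),
    class = "hill_fit"
  )
}

#' @export
print.hill_fit <- function(x, ...) {
  cat(sprintf(
    "<hill_fit> bottom %.1f, top %.1f, EC50 %.3g uM, hill %.2f (%s, %s)\n",
    x$bottom, x$top, x$ec50, x$hill, x$direction,
    if (x$converged) "converged" else "NOT converged"
  ))
  invisible(x)
}

# Evaluate a hill_fit at concentrations (uM).
predict_hill <- function(fit, conc) {
  hill_response(conc, fit$bottom, fit$top, fit$ec50, fit$hill)
}

#' Derive the 1-SD benchmark point of departure from a fitted curve
#'
#' The POD is the lowest concentration at which the fitted curve departs from
#' the vehicle mean by one vehicle standard deviation:
#' `|fit(c) - mean_pct| = sd_pct`. The crossing is located numerically by a
#' dense scan over log10 concentration followed by `uniroot()` refinement.
#' A curve that never reaches the benchmark inside
#' `(min_conc, max_conc]` is censored at `max_conc`; a curve already beyond
#' the benchmark at `min_conc` (one decade below the lowest tested
#' concentration by default) is censored low, i.e. reported as
#' "< lowest tested". Non-converged fits fall back to linear interpolation of
#' concentration-wise mean responses.
#'
#' @param fit A [fit_hill()] result.
#' @param vehicle_sd Vehicle standard deviation, % of control (> 0).
#' @param max_conc Highest tested concentration (uM): the censoring bound.
#' @param vehicle_mean Vehicle mean, % of control (100 after normalization).
#' @param min_conc Lower limit of extrapolation (uM).
#' @return A one-row tibble: `pod` (uM), `censored`, `censor_side`
#'   (`"high"`, `"low"` or `NA`), `benchmark_side` (`"above"`, `"below"` or
#'   `NA`), `method` (`"fit"` or `"interpolation"`).
#' @export
derive_pod <- function(fit, vehicle_sd, max_conc,
                       vehicle_mean = 100, min_conc = 1e-3) {
  if (!is_scalar_number(vehicle_sd) || vehicle_sd <= 0) {
    stop_toxscreen(
      "vehicle SD must be > 0 to define the benchmark response",
      "toxscreen_degenerate_error"
    )
  }
  if (!inherits(fit, "hill_fit")) {
    stop_toxscreen("fit must be a hill_fit", "toxscreen_input_error")
  }

  if (!fit$converged || fit$direction == "flat") {
    return(pod_by_interpolation(fit, vehicle_sd, max_conc, vehicle_mean))
  }

  g <- function(c) abs(predict_hill(fit, c) - vehicle_mean) - vehicle_sd
  grid <- 10^seq(log10(min_conc), log10(max_conc), length.out = 600)
  gv <- g(grid)

  if (gv[1] >= 0) {
    # already beyond the benchmark at the extrapolation floor
    return(pod_row(min_conc, TRUE, "low",
                   side_of(fit, min_conc, vehicle_mean), "fit"))
  }
  idx <- which(gv[-1] >= 0 & gv[-length(gv)] < 0)
  if (length(idx) == 0) {
    return(pod_row(max_conc, TRUE, "high", NA_character_, "fit"))
  }
  i <- idx[1]
  root <- stats::uniroot(g, lower = grid[i], upper = grid[i + 1],
                         tol = 1e-10)$root
  pod_row(root, FALSE, NA_character_, side_of(fit, root * 1.0001, vehicle_mean),
          "fit")
}

side_of <- function(fit, conc, vehicle_mean) {
  if (predict_hill(fit, conc) >= vehicle_mean) "above" else "below"
}

pod_row <- function(pod, censored, censor_side, benchmark_side, method) {
  tibble::tibble(
    pod = pod, censored = censored, censor_side = censor_side,
    benchmark_side = benchmark_side, method = method
  )
}

# Nonparametric fallback: linear interpolation of concentration-wise mean
# responses to locate the first benchmark crossing.
pod_by_interpolation <- function(fit, vehicle_sd, max_conc, vehicle_mean) {
  means <- fit$data %>%
    dplyr::group_by(.data$conc_uM) %>%
    dplyr::summarise(mu = mean(.data$response_pct), .groups = "drop") %>%
    dplyr::arrange(.data$conc_uM)
  dev <- abs(means$mu - vehicle_mean) - vehicle_sd
  if (all(dev < 0)) {
    return(pod_row(max_conc, TRUE, "high", NA_character_, "interpolation"))
  }
  first <- which(dev >= 0)[1]
  if (first == 1) {
    side <- if (means$mu[1] >= vehicle_mean) "above" else "below"
    return(pod_row(means$conc_uM[1], TRUE, "low", side, "interpolation"))
  }
  # linear interpolation in log10 concentration between the straddling pair
  x1 <- log10(means$conc_uM[first - 1]); x2 <- log10(means$conc_uM[first])
  y1 <- dev[first - 1]; y2 <- dev[first]
  root <- 10^(x1 + (0 - y1) * (x2 - x1) / (y2 - y1))
  side <- if (means$mu[first] >= vehicle_mean) "above" else "below"
  pod_row(root, FALSE, NA_character_, side, "interpolation")
}

#' Fit Hill curves and derive PODs for a whole screen
#'
#' Runs [fit_hill()] and [derive_pod()] for every chemical x phenotype in a
#' normalized screen, using the plate-matched vehicle standard deviation per
#' phenotype as the benchmark. This produces the POD table, the pipeline's
#' central exchange object.
#'
#' Chemical x phenotype pairs whose response shows no statistically
#' supported concentration dependence (Hill-vs-flat F-test p above
#' `hit_alpha`) are treated as inactive and censored at the maximum tested
#' concentration rather than assigned a spurious benchmark crossing from a
#' noise-fitted curve.
#'
#' @param normalized A [normalize_to_vehicle()] result, or a list with
#'   `measurements` and `vehicle_stats` in the same layout.
#' @param vehicle_ids Chemical ids to exclude as controls.
#' @param hit_alpha Significance level of the activity call (default 0.01);
#'   set to 1 to disable the gate and derive a POD from every fit.
#' @return A tibble of class `pod_table`: one row per chemical x phenotype
#'   with `chemical`, `class`, `cell_type`, `phenotype`, `category`, `pod`
#'   (uM), `censored`, `censor_side`, `benchmark_side`, `method`,
#'   `converged`, `vehicle_sd`. The censoring bound (maximum tested
#'   concentration) is stored in the `max_conc` attribute.
#' @export
fit_pod_table <- function(normalized,
                          vehicle_ids = c("vehicle_control", "medium_control"),
                          hit_alpha = 0.01) {
  meas <- normalized$measurements %>%
    dplyr::filter(!(.data$chemical %in% vehicle_ids), .data$conc_uM > 0)
  vstats <- normalized$vehicle_stats
  max_conc <- max(meas$conc_uM)

  pods <- meas %>%
    dplyr::group_by(.data$chemical, .data$class, .data$cell_type,
                    .data$phenotype, .data$category, .data$plate) %>%
    dplyr::group_modify(function(df, key) {
      sd_v <- vstats$sd_pct[vstats$plate == key$plate &
                              vstats$phenotype == key$phenotype]
      fit <- fit_hill(df$conc_uM, df$response_pct)
      res <- if (fit$f_pvalue < hit_alpha) {
        derive_pod(fit, sd_v, max_conc)
      } else {
        pod_row(max_conc, TRUE, "high", NA_character_, "inactive")
      }
      res$converged <- fit$converged
      res$vehicle_sd <- sd_v
      res
    }) %>%
    dplyr::ungroup() %>%
    dplyr::select(-"plate")

  structure(pods, class = c("pod_table", class(pods)), max_conc = max_conc)
}
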