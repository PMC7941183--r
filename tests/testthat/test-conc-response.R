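test_that("vehicle normalization anchors the plate mean at 100%", {
  base <- tibble::tibble(
    chemical = c("A", "A", "vehicle_control", "vehicle_control"),
    cell_type = "hepatocyte", phenotype = "p1", category = "cytotoxicity",
    plate = "plate_1", conc_uM = c(10, 1, 0, 0), replicate = c(1, 1, 1, 2),
    response_pct = c(800, 900, 990, 1010)
  )
  norm <- normalize_to_vehicle(base)
  expect_equal(norm$vehicle_stats$mean_pct, 100)
  expect_equal(norm$vehicle_stats$sd_pct, 100 * sd(c(990, 1010)) / 1000)
  expect_equal(norm$measurements$response_pct[1], 80)

  # missing vehicle wells name the offending plate/phenotype
  err <- expect_error(normalize_to_vehicle(base[base$conc_uM > 0, ]),
                      class = "toxscreen_qc_error")
  expect_match(conditionMessage(err), "plate_1/p1")

  # identical vehicle wells: normalization succeeds with sd 0, but the
  # benchmark cannot be defined downstream
  flat <- base
  flat$response_pct[3:4] <- 1000
  norm0 <- normalize_to_vehicle(flat)
  expect_equal(norm0$vehicle_stats$sd_pct, 0)
  fit <- make_hill_fit(100, 40, 1, 1)
  expect_error(derive_pod(fit, vehicle_sd = 0, max_conc = 100),
               class = "toxscreen_degenerate_error")
})

test_that("Hill fits recover noiseless curve parameters", {
  conc <- rep(c(100, 10, 1, 0.1, 0.01), each = 3)
  set.seed(11)
  for (i in 1:20) {
    top <- sample(c(runif(1, 30, 70), runif(1, 130, 170)), 1)
    ec50 <- 10^runif(1, -1.5, 1.5)
    hill <- runif(1, 0.8, 3)
    fit <- fit_hill(conc, hill_response(conc, 100, top, ec50, hill))
    expect_true(fit$converged)
    expect_equal(fit$top, top, tolerance = 1e-3)
    expect_equal(fit$ec50, ec50, tolerance = 1e-3)
    expect_equal(fit$hill, hill, tolerance = 1e-3)
    expect_equal(fit$direction,
                 if (top > 100) "increasing" else "decreasing")
    expect_lt(fit$f_pvalue, 1e-6)
  }
})

test_that("flat and insufficient data are handled honestly", {
  conc <- rep(c(100, 10, 1, 0.1, 0.01), each = 3)
  set.seed(3)
  flat <- fit_hill(conc, rnorm(length(conc), 100, 5))
  expect_equal(flat$top, flat$bottom, tolerance = 12)
  expect_gt(flat$f_pvalue, 0.001)
  expect_error(fit_hill(c(1, 10, 100), c(90, 80, 70)),
               class = "toxscreen_insufficient_data_error")
})

test_that("derived POD matches the closed form and censors at the bounds", {
  fit <- make_hill_fit(100, 40, 1, 1)
  res <- derive_pod(fit, vehicle_sd = 5, max_conc = 100)
  expect_equal(res$pod, 1 / 11, tolerance = 1e-6)
  expect_false(res$censored)
  expect_equal(res$benchmark_side, "below")

  # plateau short of the benchmark: censored at the top concentration
  res2 <- derive_pod(make_hill_fit(100, 96, 1, 1), vehicle_sd = 5,
                     max_conc = 100)
  expect_true(res2$censored)
  expect_equal(res2$censor_side, "high")
  expect_equal(res2$pod, 100)

  # crossing below the extrapolation floor: reported as "< lowest tested"
  res3 <- derive_pod(make_hill_fit(100, 20, 1e-4, 1), vehicle_sd = 5,
                     max_conc = 100)
  expect_true(res3$censored)
  expect_equal(res3$censor_side, "low")
})

test_that("numeric POD equals the grid-plus-bisection oracle on random fits", {
  set.seed(202)
  n_ok <- 0
  for (i in 1:300) {
    top <- sample(c(runif(1, 20, 94), runif(1, 106, 180)), 1)
    ec50 <- 10^runif(1, -3, 3)
    hill <- runif(1, 0.3, 6)
    fit <- make_hill_fit(100, top, ec50, hill)
    res <- derive_pod(fit, vehicle_sd = 5, max_conc = 100)
    oracle <- pod_bisection_oracle(100, top, ec50, hill, 5)
    if (res$censored) {
      expect_true(!is.finite(oracle) || oracle <= 1.01e-3 ||
                    res$censor_side == "high")
    } else {
      expect_equal(res$pod, oracle, tolerance = 1e-4)
      n_ok <- n_ok + 1
    }
  }
  expect_gt(n_ok, 100)
})

test_that("fit-then-derive agrees with the analytic POD on noiseless data", {
  conc <- rep(c(100, 10, 1, 0.1, 0.01), each = 3)
  set.seed(4)
  checked <- 0
  for (i in 1:30) {
    top <- sample(c(runif(1, 30, 80), runif(1, 120, 170)), 1)
    ec50 <- 10^runif(1, -1, 1.5)
    hill <- runif(1, 0.8, 3)
    fit <- fit_hill(conc, hill_response(conc, 100, top, ec50, hill))
    truth <- analytic_pod(top, ec50, hill, vehicle_sd = 5)
    res <- derive_pod(fit, vehicle_sd = 5, max_conc = 100)
    if (is.finite(truth) && truth > 1.1e-3 && truth < 100) {
      expect_equal(res$pod, truth, tolerance = 1e-3)
      checked <- checked + 1
    }
  }
  expect_gt(checked, 15)
})

test_that("POD estimation is robust to 10% well noise", {
  scr <- small_screen(seed = 101, noise_sd = 10)
  pods <- small_pods(seed = 101, noise_sd = 10)
  truth <- scr$truth %>%
    dplyr::mutate(pod_true = analytic_pod(top, ec50, hill, vehicle_sd = 10,
                                          active = active))
  joined <- pods %>%
    dplyr::inner_join(truth[, c("chemical", "phenotype", "pod_true")],
                      by = c("chemical", "phenotype")) %>%
    dplyr::filter(is.finite(pod_true), pod_true > 0.01, pod_true < 100,
                  !censored)
  expect_gt(nrow(joined), 20)
  err <- abs(log10(joined$pod / joined$pod_true))
  expect_lt(median(err), 0.25)
})

test_that("the activity gate censors flat curves instead of calling noise", {
  scr <- small_screen(seed = 101, noise_sd = 10)
  pods <- small_pods(seed = 101, noise_sd = 10)
  joined <- pods %>%
    dplyr::inner_join(scr$truth[, c("chemical", "phenotype", "active")],
                      by = c("chemical", "phenotype"))
  fp <- joined %>% dplyr::filter(!active)
  expect_lt(mean(!fp$censored), 0.05)
})

test_that("functional phenotypes rank as more sensitive when planted so", {
  pods <- tibble::tibble(
    chemical = rep(paste0("c", 1:6), 2),
    cell_type = "hepatocyte",
    phenotype = rep(c("f1", "c1"), each = 6),
    category = rep(c("functional", "cytotoxicity"), each = 6),
    pod = c(rep(0.1, 6), rep(10, 6)),
    censored = FALSE
  )
  res <- phenotype_category_contrast(pods)
  hep <- res[res$cell_type == "hepatocyte", ]
  expect_lt(hep$p_value, 0.05)
  expect_true(hep$evaluable)

  # single POD per category: computed but flagged
  tiny <- pods[c(1, 7), ]
  res2 <- phenotype_category_contrast(tiny)
  expect_true(all(res2$low_n))
  expect_true(all(res2$evaluable))

  # a missing category is not evaluable
  res3 <- phenotype_category_contrast(pods[pods$category == "functional", ])
  expect_false(any(res3$evaluable))
})

test_that("category contrast p-values are calibrated under the null", {
  set.seed(9)
  pvals <- replicate(60, {
    pods <- tibble::tibble(
      chemical = paste0("c", 1:20),
      cell_type = "hepatocyte",
      phenotype = paste0("p", 1:20),
      category = rep(c("functional", "cytotoxicity"), each = 10),
      pod = 10^rnorm(20, 0, 1),
      censored = FALSE
    )
    phenotype_category_contrast(pods)$p_value[1]
  })
  # one-sided p under identical distributions should be roughly uniform
  expect_gt(mean(pvals), 0.3)
  expect_lt(mean(pvals), 0.7)
})
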