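toy_pods <- function() {
  tibble::tibble(
    chemical = rep(c("a", "b"), each = 3),
    cell_type = rep(c("hepatocyte", "hepatocyte", "neuron"), 2),
    phenotype = rep(c("p1", "p2", "p3"), 2),
    pod = c(0.5, 10, 100, 100, 100, 100),
    censored = c(FALSE, FALSE, TRUE, TRUE, TRUE, TRUE),
    censor_side = c(NA, NA, "high", "high", "high", "high")
  )
}

test_that("surrogate POD is the minimum with censoring propagation", {
  sur <- surrogate_pod(toy_pods(), "all")
  expect_equal(sur$pod[sur$chemical == "a"], 0.5)
  expect_false(sur$censored[sur$chemical == "a"])
  # all-censored chemical: censored surrogate at the bound, flagged
  expect_equal(sur$pod[sur$chemical == "b"], 100)
  expect_true(sur$censored[sur$chemical == "b"])
  expect_error(surrogate_pod(toy_pods(), "cardiomyocyte"),
               class = "toxscreen_input_error")
})

test_that("narrowing the scope never decreases the surrogate POD", {
  set.seed(12)
  for (i in 1:20) {
    pods <- tidyr::expand_grid(
      chemical = paste0("c", 1:5),
      tibble::tibble(cell_type = rep(c("s1", "s2", "s3"), each = 2),
                     phenotype = paste0("p", 1:6))
    ) %>%
      dplyr::mutate(pod = 10^runif(dplyr::n(), -2, 2),
                    censored = runif(dplyr::n()) < 0.2,
                    censor_side = ifelse(censored, "high", NA_character_),
                    pod = ifelse(censored, 100, pod))
    all_s <- surrogate_pod(pods, "all")
    for (ct in c("s1", "s2", "s3")) {
      one <- surrogate_pod(pods, ct)
      j <- dplyr::inner_join(all_s, one, by = "chemical",
                             suffix = c("_all", "_one"))
      expect_true(all(j$pod_all <= j$pod_one + 1e-12))
    }
  }
})

test_that("dose conversions are linear and invert exactly", {
  expect_equal(pod_to_aed(10, 2), 5)
  expect_equal(dose_to_css(pod_to_aed(10, 2), 2), 10)
  expect_equal(pod_to_aed(10, 1), 2 * pod_to_aed(10, 2))
  expect_error(pod_to_aed(10, 0), class = "toxscreen_input_error")
})

test_that("conservatism comparison reproduces a planted 25% fraction", {
  nam <- tibble::tibble(chemical = paste0("c", 1:4),
                        pod_aed = c(0.1, 0.2, 0.3, 5))
  invivo <- tibble::tibble(chemical = paste0("c", 1:4),
                           pod_rfd = c(1, 1, 1, 1))
  res <- conservatism_comparison(nam, invivo)
  expect_equal(res$frac_unconservative, 0.25)
  expect_equal(res$frac_unconservative_within_10x, 1)
  expect_equal(res$ratios$log10_ratio[4], log10(5))

  # equal PODs: strictly-greater test flags nothing
  res_eq <- conservatism_comparison(invivo %>% dplyr::rename(pod_aed = pod_rfd),
                                    invivo)
  expect_equal(res_eq$frac_unconservative, 0)
  expect_true(all(res_eq$ratios$log10_ratio == 0))

  # ten-fold lower NAM PODs: fully conservative, ratios -1
  res_c <- conservatism_comparison(
    dplyr::mutate(invivo, pod_aed = pod_rfd / 10), invivo
  )
  expect_equal(res_c$frac_unconservative, 0)
  expect_true(all(res_c$ratios$log10_ratio == -1))

  # declared units are audited, not guessed
  expect_error(conservatism_comparison(nam, invivo, nam_units = "uM"),
               class = "toxscreen_unit_error")
  expect_error(
    conservatism_comparison(nam, invivo[0, ]),
    class = "toxscreen_input_error"
  )
})

test_that("MoE uses a strict benchmark and propagates censored bounds", {
  rec <- tibble::tibble(
    chemical = c("a", "b", "c", "d"),
    pod_aed = c(5, 5, 5, 5),
    exposure = c(0.05, 0.5, 0, 0.1),
    censored = c(FALSE, FALSE, FALSE, TRUE)
  )
  moe <- margin_of_exposure(rec)
  # MoE exactly 100 is NOT of concern (strict <)
  expect_equal(moe$moe[1], 100)
  expect_false(moe$concern[1])
  expect_equal(moe$moe[2], 10)
  expect_true(moe$concern[2])
  # zero exposure: infinite MoE, not flagged
  expect_equal(moe$moe[3], Inf)
  expect_false(moe$concern[3])
  # censored lower bound flagged in conservative mode only
  expect_true(moe$moe_is_lower_bound[4])
  expect_true(moe$concern[4])
  lax <- margin_of_exposure(rec, conservative = FALSE)
  expect_false(lax$concern[4])

  expect_error(margin_of_exposure(dplyr::mutate(rec, exposure = -1)),
               class = "toxscreen_input_error")
})

test_that("MoE is monotone in POD and exposure", {
  set.seed(14)
  for (i in 1:25) {
    pod <- runif(1, 0.1, 10); expo <- runif(1, 1e-4, 1e-1)
    base <- margin_of_exposure(tibble::tibble(
      chemical = "x", pod_aed = pod, exposure = expo
    ))$moe
    lower_pod <- margin_of_exposure(tibble::tibble(
      chemical = "x", pod_aed = pod * runif(1, 0.1, 1), exposure = expo
    ))$moe
    lower_exp <- margin_of_exposure(tibble::tibble(
      chemical = "x", pod_aed = pod, exposure = expo * runif(1, 0.1, 1)
    ))$moe
    expect_lte(lower_pod, base)
    expect_gte(lower_exp, base)
  }
})

test_that("the end-to-end MoE screen drops chemicals without TK data", {
  pods <- toy_pods()
  tk <- tibble::tibble(chemical = "a", css_per_unit_dose = 2,
                       exposure = 0.001)
  expect_message(moe <- moe_screen(pods, tk), "dropped")
  expect_equal(nrow(moe), 1)
  expect_equal(moe$pod_aed, 0.25)
  expect_equal(moe$moe, 250)
})

test_that("the packaged synthetic TK fixture supports the full risk path", {
  tk <- synthetic_tk_table()
  expect_true(all(tk$css_per_unit_dose > 0))
  expect_true(all(tk$exposure >= 0))
  nam <- tibble::tibble(chemical = tk$chemical,
                        pod_aed = pod_to_aed(1, tk$css_per_unit_dose))
  res <- conservatism_comparison(nam, tk)
  expect_equal(res$n, nrow(tk))
})
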