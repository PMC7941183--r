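pods_from_values <- function(values, censored = rep(FALSE, length(values)),
                             phenotype = "p1", cell_type = "hepatocyte") {
  tibble::tibble(
    chemical = paste0("c", seq_along(values)),
    cell_type = cell_type, phenotype = phenotype,
    pod = values, censored = censored,
    censor_side = ifelse(censored, "high", NA_character_)
  )
}

test_that("PODs scale inversely onto [0,1] with log10 interpolation", {
  sc <- scale_pod_matrix(pods_from_values(c(0.01, 1, 100)))
  expect_equal(sc$score, c(1, 0.5, 0))

  # linear mode interpolates on the raw scale
  sc_lin <- scale_pod_matrix(pods_from_values(c(0.01, 1, 100)), "linear")
  expect_equal(sc_lin$score[1], 1)
  expect_equal(sc_lin$score[3], 0)
  expect_equal(sc_lin$score[2], (100 - 1) / (100 - 0.01))

  # censored chemical among finite PODs scores exactly 0
  sc_c <- scale_pod_matrix(pods_from_values(c(0.1, 10, 100),
                                            censored = c(FALSE, FALSE, TRUE)))
  expect_identical(sc_c$score[3], 0)

  # all PODs equal: degenerate column, all-0 and flagged
  expect_warning(
    sc_eq <- scale_pod_matrix(pods_from_values(c(1, 1, 1))),
    "all-0"
  )
  expect_true(all(sc_eq$score == 0))
  expect_equal(attr(sc_eq, "flagged_phenotypes"), "p1")
})

test_that("log10-mode scores are invariant to rescaling a phenotype's PODs", {
  set.seed(21)
  vals <- 10^runif(8, -2, 2)
  s1 <- scale_pod_matrix(pods_from_values(vals))
  s2 <- scale_pod_matrix(pods_from_values(vals * 37.5))
  expect_equal(s1$score, s2$score, tolerance = 1e-12)
})

test_that("slice and overall scores aggregate as weighted means with deterministic ranks", {
  scores <- tibble::tibble(
    chemical = "c1",
    slice = paste0("s", 1:5),
    phenotype = paste0("p", 1:5),
    score = c(0.2, 0.4, 0.6, 0.8, 1.0)
  )
  prof <- toxpi_profile(scores)
  expect_equal(unique(prof$overall_score), 0.6)

  # all-zero chemical ranks last; ties broken by chemical id
  scores2 <- tidyr::expand_grid(chemical = c("b", "a", "z"),
                                slice = "s1", phenotype = c("p1", "p2")) %>%
    dplyr::mutate(score = ifelse(chemical == "z", 0, 0.5))
  prof2 <- toxpi_profile(scores2)
  ranks <- dplyr::distinct(prof2, chemical, rank)
  expect_equal(ranks$rank[ranks$chemical == "z"], 3)
  expect_lt(ranks$rank[ranks$chemical == "a"], ranks$rank[ranks$chemical == "b"])

  expect_error(toxpi_profile(scores, weights = c(s1 = 1)),
               class = "toxscreen_config_error")
})

test_that("scores stay in [0,1] and match a direct recomputation", {
  pods <- small_pods()
  # sparse phenotypes with < 2 observed PODs are legitimately flagged here
  sc <- suppressWarnings(scale_pod_matrix(pods))
  expect_true(all(sc$score >= 0 & sc$score <= 1))
  prof <- toxpi_profile(sc)
  expect_true(all(prof$slice_score >= 0 & prof$slice_score <= 1))
  expect_true(all(prof$overall_score >= 0 & prof$overall_score <= 1))

  # independent recomputation from the scaled matrix
  direct <- tapply(sc$score, list(sc$chemical, sc$slice), mean)
  for (i in seq_len(nrow(prof))) {
    expect_equal(prof$slice_score[i],
                 direct[prof$chemical[i], prof$slice[i]],
                 tolerance = 1e-12)
  }
  overall_direct <- rowMeans(direct)
  ov <- dplyr::distinct(prof, chemical, overall_score)
  expect_equal(ov$overall_score, unname(overall_direct[ov$chemical]),
               tolerance = 1e-12)

  # ranks are a permutation of 1..n
  expect_setequal(dplyr::distinct(prof, chemical, rank)$rank,
                  seq_len(dplyr::n_distinct(prof$chemical)))
})

test_that("lowering one POD never decreases that chemical's overall score", {
  set.seed(31)
  for (rep in 1:15) {
    n_chem <- 6; n_phen <- 4
    pods <- tidyr::expand_grid(chemical = paste0("c", 1:n_chem),
                               phenotype = paste0("p", 1:n_phen)) %>%
      dplyr::mutate(
        cell_type = ifelse(phenotype %in% c("p1", "p2"), "s1", "s2"),
        pod = 10^runif(dplyr::n(), -2, 2),
        censored = FALSE, censor_side = NA_character_
      )
    target_chem <- sample(pods$chemical, 1)
    target_phen <- sample(pods$phenotype, 1)
    i <- which(pods$chemical == target_chem & pods$phenotype == target_phen)
    before <- toxpi_profile(scale_pod_matrix(pods))
    pods2 <- pods
    pods2$pod[i] <- pods2$pod[i] / 10^runif(1, 0.1, 2)
    after <- toxpi_profile(scale_pod_matrix(pods2))
    ov_b <- dplyr::distinct(before, chemical, overall_score)
    ov_a <- dplyr::distinct(after, chemical, overall_score)
    expect_gte(
      ov_a$overall_score[ov_a$chemical == target_chem] -
        ov_b$overall_score[ov_b$chemical == target_chem],
      -1e-12
    )
  }
})

test_that("class score ranges summarize and rank classes by median overall", {
  scores <- tidyr::expand_grid(chemical = c("a1", "a2", "b1"),
                               slice = "s1", phenotype = c("p1", "p2")) %>%
    dplyr::mutate(score = c(0.1, 0.1, 0.3, 0.3, 0.9, 0.9))
  prof <- toxpi_profile(scores)
  classing <- tibble::tibble(chemical = c("a1", "a2", "b1"),
                             class = c("A", "A", "B"))
  rng <- class_score_ranges(prof, classing)
  a_overall <- rng[rng$class == "A" & rng$slice == "overall", ]
  expect_equal(a_overall$min, 0.1)
  expect_equal(a_overall$max, 0.3)
  # single-chemical class has a degenerate range
  b_overall <- rng[rng$class == "B" & rng$slice == "overall", ]
  expect_equal(b_overall$min, b_overall$max)
  expect_equal(b_overall$class_rank, 1)

  expect_error(class_score_ranges(prof, classing[1:2, ]),
               class = "toxscreen_input_error")
})
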