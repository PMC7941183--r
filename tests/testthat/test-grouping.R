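test_that("duplicated chemicals merge first; anti-correlated vectors get distance 2", {
  m <- tibble::tibble(
    chemical = c("a", "b", "c", "d"),
    f1 = c(1, 1, 5, 2), f2 = c(2, 2, 1, 9), f3 = c(3, 3, 0, 4)
  )
  cl <- cluster_chemicals(m, k = 2)
  # identical rows have correlation distance 0 and merge at height 0
  expect_equal(cl$tree$height[1], 0, tolerance = 1e-12)
  part <- setNames(cl$partition$cluster, cl$partition$chemical)
  expect_equal(part[["a"]], part[["b"]])

  # 1 - r is not clipped: perfect anti-correlation gives 2
  anti <- rbind(x = c(1, 2, 3), y = c(3, 2, 1), z = c(1, 2, 4))
  tr <- cluster_chemicals(anti, k = 2)$tree
  # average-linkage merge of y with {x,z} sits near 2, well above a
  # [0,1]-clipped range
  expect_gt(max(tr$height), 1.9)
  expect_error(cluster_chemicals(anti, k = 3), class = "toxscreen_input_error")

  # constant rows warn and take maximal dissimilarity
  const <- tibble::tibble(chemical = c("a", "b", "c"),
                          f1 = c(1, 1, 5), f2 = c(1, 2, 1), f3 = c(1, 3, 0))
  expect_warning(cluster_chemicals(const, k = 2), "constant")
})

test_that("planted feature blocks are recovered exactly", {
  set.seed(41)
  classes <- rep(1:5, times = c(4, 6, 3, 5, 4))
  n <- length(classes)
  m <- matrix(rnorm(n * 20, 0, 0.1), n, 20)
  for (k in 1:5) m[classes == k, (4 * k - 3):(4 * k)] <- 5
  rownames(m) <- paste0("chem", seq_len(n))
  cl <- cluster_chemicals(m, k = 5)
  truth <- setNames(classes, rownames(m))
  fm <- fm_index(cl, truth)
  expect_equal(fm$B, 1)
})

test_that("FM index follows its pair-count definition", {
  a <- setNames(c(1, 1, 2, 2), letters[1:4])
  expect_equal(fm_index(a, a)$B, 1)

  # no shared co-clustered pair: Tk = 0, B = 0
  b <- setNames(c(1, 2, 1, 2), letters[1:4])
  res <- fm_index(a, b)
  expect_equal(res$Tk, 0)
  expect_equal(res$B, 0)

  # all singletons is undefined
  expect_error(fm_index(a, setNames(1:4, letters[1:4])),
               class = "toxscreen_degenerate_error")
  expect_error(fm_index(a, setNames(c(1, 1, 2), c("a", "b", "x"))),
               class = "toxscreen_input_error")
})

test_that("FM index equals brute-force pair enumeration on random partitions", {
  set.seed(51)
  for (i in 1:200) {
    n <- sample(4:12, 1)
    a <- random_partition(n, sample(2:4, 1))
    b <- random_partition(n, sample(2:4, 1))
    names(a) <- names(b) <- paste0("i", seq_len(n))
    expect_equal(fm_index(a, b)$B, fm_oracle(a, b), tolerance = 1e-12)
  }
})

test_that("FM is invariant to item order and cluster relabeling", {
  set.seed(61)
  n <- 15
  a <- setNames(random_partition(n, 3), paste0("i", 1:n))
  b <- setNames(random_partition(n, 4), paste0("i", 1:n))
  base <- fm_index(a, b)$B
  perm <- sample(n)
  expect_equal(fm_index(a[perm], b[perm])$B, base, tolerance = 1e-12)
  relabeled <- setNames(c(9, 3, 7, 5)[b], names(b))
  expect_equal(fm_index(a, relabeled)$B, base, tolerance = 1e-12)
})

test_that("analytic null expectation matches exhaustive relabeling for n = 4", {
  a <- setNames(c(1, 1, 2, 2), letters[1:4])
  res <- fm_significance(fm_index(a, a), mode = "analytic")
  expect_equal(res$expected_B, 1 / 3, tolerance = 1e-12)

  # exhaustive oracle: average B over all 4! item permutations of b
  perms <- rbind(
    c(1,2,3,4), c(1,2,4,3), c(1,3,2,4), c(1,3,4,2), c(1,4,2,3), c(1,4,3,2),
    c(2,1,3,4), c(2,1,4,3), c(2,3,1,4), c(2,3,4,1), c(2,4,1,3), c(2,4,3,1),
    c(3,1,2,4), c(3,1,4,2), c(3,2,1,4), c(3,2,4,1), c(3,4,1,2), c(3,4,2,1),
    c(4,1,2,3), c(4,1,3,2), c(4,2,1,3), c(4,2,3,1), c(4,3,1,2), c(4,3,2,1)
  )
  vals <- apply(perms, 1, function(p) fm_oracle(unname(a), unname(a)[p]))
  expect_equal(mean(vals), 1 / 3, tolerance = 1e-12)
})

test_that("permutation null mean agrees with the analytic expectation", {
  set.seed(71)
  for (i in 1:25) {
    n <- sample(10:30, 1)
    a <- setNames(random_partition(n, sample(2:5, 1)), paste0("i", 1:n))
    b <- setNames(random_partition(n, sample(2:5, 1)), paste0("i", 1:n))
    ana <- fm_significance(fm_index(a, b), mode = "analytic")
    # independent draw of the null: relabel b uniformly, recompute B
    draws <- vapply(1:500, function(j) {
      fm_index(a, setNames(sample(unname(b)), names(b)))$B
    }, numeric(1))
    se <- sd(draws) / sqrt(length(draws))
    expect_lt(abs(mean(draws) - ana$expected_B), 3 * se + 1e-9)
  }
})

test_that("analytic and permutation z statistics agree for n >= 20", {
  set.seed(81)
  for (i in 1:8) {
    n <- sample(20:35, 1)
    a <- setNames(random_partition(n, 4), paste0("i", 1:n))
    # associated partition: relabel a few items so B is clearly above null
    b <- a
    flip <- sample(n, 4)
    b[flip] <- sample(1:4, 4, replace = TRUE)
    obs <- fm_index(a, b)
    ana <- fm_significance(obs, mode = "analytic")
    perm <- fm_significance(obs, mode = "permutation", n_perm = 4000, seed = i)
    expect_lt(abs(ana$z - perm$z) / abs(perm$z), 0.15)
  }
})

test_that("tiny partitions fall back to permutation mode", {
  a <- setNames(c(1, 1, 2), c("x", "y", "z"))
  expect_message(
    res <- fm_significance(fm_index(a, a), mode = "analytic"),
    "permutation"
  )
  expect_equal(res$null_mode, "permutation")
  expect_true(res$p_value > 0 && res$p_value <= 1)
})
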