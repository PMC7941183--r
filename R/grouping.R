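#' Convert long component scores to a chemicals x features matrix
#'
#' Widens a long score or POD table into the numeric feature matrix used by
#' the grouping and classification stages. Missing features (e.g. a chemical
#' untested in an external assay set) are mean-imputed per feature, with a
#' message reporting the count.
#'
#' @param scores Long tibble with `chemical`, a feature id column, and a
#'   value column.
#' @param feature_col,value_col Names of the feature-id and value columns.
#' @return A tibble with one row per chemical: `chemical` plus one numeric
#'   column per feature.
#' @export
as_feature_matrix <- function(scores, feature_col = "phenotype",
                              value_col = "score") {
  assert_columns(scores, c("chemical", feature_col, value_col), "score table")
  wide <- scores %>%
    dplyr::select(dplyr::all_of(c("chemical", feature_col, value_col))) %>%
    tidyr::pivot_wider(names_from = dplyr::all_of(feature_col),
                       values_from = dplyr::all_of(value_col))
  n_missing <- sum(is.na(wide[-1]))
  if (n_missing > 0) {
    inform(sprintf("mean-imputed %d missing feature value(s)", n_missing))
    wide[-1] <- lapply(wide[-1], function(x) {
      x[is.na(x)] <- mean(x, na.rm = TRUE)
      x
    })
  }
  wide
}

feature_matrix_to_matrix <- function(features) {
  if (is.matrix(features)) {
    if (is.null(rownames(features))) {
      stop_toxscreen("feature matrix needs chemical rownames",
                     "toxscreen_input_error")
    }
    return(features)
  }
  assert_columns(features, "chemical", "feature matrix")
  m <- as.matrix(features[, setdiff(names(features), "chemical"), drop = FALSE])
  if (!is.numeric(m)) {
    stop_toxscreen("feature columns must be numeric", "toxscreen_input_error")
  }
  rownames(m) <- features$chemical
  m
}

#' Hierarchically cluster chemicals from a feature matrix
#'
#' Agglomerative clustering of chemicals using either correlation distance
#' (`1 - Pearson r` between chemical feature vectors, range [0, 2], not
#' clipped) or Euclidean distance, with average or Ward ("ward.D") linkage,
#' cut into `k` groups. A chemical with a constant feature vector has no
#' defined correlation; its correlation distance is set to the maximal
#' dissimilarity of 1 with a warning.
#'
#' @param features Chemicals x features tibble (see [as_feature_matrix()])
#'   or numeric matrix with chemical rownames.
#' @param k Number of groups, in `[2, n - 1]`.
#' @param distance `"pearson"` or `"euclidean"`.
#' @param linkage `"average"` or `"ward"`.
#' @return An object of class `chem_clustering`: `partition` (tibble
#'   `chemical`, `cluster`), `tree` (an [stats::hclust] dendrogram),
#'   `distance`, `linkage`, `k`.
#' @export
cluster_chemicals <- function(features, k = 5,
                              distance = c("pearson", "euclidean"),
                              linkage = c("average", "ward")) {
  distance <- match.arg(distance)
  linkage <- match.arg(linkage)
  m <- feature_matrix_to_matrix(features)
  n <- nrow(m)
  if (n < 2) {
    stop_toxscreen("clustering needs >= 2 chemicals", "toxscreen_input_error")
  }
  if (k < 2 || k > n - 1) {
    stop_toxscreen("k must lie in [2, n - 1]", "toxscreen_input_error")
  }

  if (distance == "pearson") {
    sds <- apply(m, 1, stats::sd)
    d <- matrix(1, n, n, dimnames = list(rownames(m), rownames(m)))
    ok <- sds > 0
    if (any(!ok)) {
      warn(sprintf(
        "%d chemical(s) have constant feature vectors; their correlation distance is set to 1",
        sum(!ok)
      ))
    }
    if (sum(ok) >= 2) {
      d[ok, ok] <- 1 - stats::cor(t(m[ok, , drop = FALSE]))
    }
    diag(d) <- 0
    dd <- stats::as.dist(d)
  } else {
    dd <- stats::dist(m, method = "euclidean")
  }

  tree <- stats::hclust(dd, method = if (linkage == "ward") "ward.D" else "average")
  cut <- stats::cutree(tree, k = k)
  structure(
    list(
      partition = tibble::tibble(chemical = names(cut),
                                 cluster = unname(cut)),
      tree = tree, distance = distance, linkage = linkage, k = k
    ),
    class = "chem_clustering"
  )
}

#' @export
print.chem_clustering <- function(x, ...) {
  cat(sprintf("<chem_clustering> %d chemicals into %d groups (%s distance, %s linkage)\n",
              nrow(x$partition), x$k, x$distance, x$linkage))
  print(table(x$partition$cluster))
  invisible(x)
}

# Coerce a partition (named vector, factor, or tibble chemical/cluster)
# into an integer code vector named by item.
as_partition <- function(p) {
  if (inherits(p, "chem_clustering")) p <- p$partition
  if (is.data.frame(p)) {
    assert_columns(p, "chemical", "partition")
    label_col <- setdiff(names(p), "chemical")[1]
    v <- setNames(as.character(p[[label_col]]), p$chemical)
  } else if (!is.null(names(p))) {
    v <- setNames(as.character(p), names(p))
  } else {
    stop_toxscreen("partitions must carry item names", "toxscreen_input_error")
  }
  setNames(as.integer(factor(v)), names(v))
}

#' Fowlkes-Mallows index between two partitions
#'
#' Pair-counting similarity between two partitions of the same chemicals.
#' With contingency counts `m_ij` between the groups of the two partitions,
#' `Tk = sum(m_ij^2) - n`, `Pk = sum(rowsums^2) - n`,
#' `Qk = sum(colsums^2) - n`, and `B = Tk / sqrt(Pk * Qk)`. `B` is 1 exactly
#' when the two partitions are identical up to relabeling and 0 when no
#' co-clustered pair is shared. Complete significance with
#' [fm_significance()].
#'
#' @param partition_a,partition_b Partitions of the same items: a
#'   [cluster_chemicals()] result, a tibble with `chemical` and a label
#'   column, or a named vector of labels.
#' @return An object of class `fm_result` with `B`, `Tk`, `Pk`, `Qk`, `n`,
#'   and (after [fm_significance()]) `expected_B`, `z`, `p_value`,
#'   `null_mode`, `n_permutations`.
#' @export
#' @examples
#' ref <- atsdr_chemicals()
#' fm_index(ref, ref)$B # identical partitions: 1
fm_index <- function(partition_a, partition_b) {
  a <- as_partition(partition_a)
  b <- as_partition(partition_b)
  if (!setequal(names(a), names(b))) {
    stop_toxscreen("partitions must cover the same chemicals",
                   "toxscreen_input_error")
  }
  b <- b[names(a)]
  n <- length(a)
  tab <- table(a, b)
  Tk <- sum(tab^2) - n
  Pk <- sum(rowSums(tab)^2) - n
  Qk <- sum(colSums(tab)^2) - n
  if (Pk == 0 || Qk == 0) {
    stop_toxscreen(
      "FM index is undefined when a partition consists entirely of singletons",
      "toxscreen_degenerate_error"
    )
  }
  B <- if (Tk == 0) 0 else Tk / sqrt(Pk * Qk)
  structure(
    list(B = B, Tk = Tk, Pk = Pk, Qk = Qk, n = n,
         partition_a = a, partition_b = b,
         expected_B = NA_real_, z = NA_real_, p_value = NA_real_,
         null_mode = NA_character_, n_permutations = NA_integer_),
    class = "fm_result"
  )
}

# Null moments of Tk/Bk under random relabeling (Fowlkes & Mallows 1983).
fm_analytic_moments <- function(Pk, Qk, n, a_sizes, b_sizes) {
  Pk2 <- sum(a_sizes * (a_sizes - 1) * (a_sizes - 2))
  Qk2 <- sum(b_sizes * (b_sizes - 1) * (b_sizes - 2))
  e_B <- sqrt(Pk * Qk) / (n * (n - 1))
  var_B <- 2 / (n * (n - 1)) +
    4 * Pk2 * Qk2 / (n * (n - 1) * (n - 2) * Pk * Qk) +
    (Pk - 2 - 4 * Pk2 / Pk) * (Qk - 2 - 4 * Qk2 / Qk) /
      (n * (n - 1) * (n - 2) * (n - 3)) -
    Pk * Qk / (n^2 * (n - 1)^2)
  list(expected_B = e_B, var_B = var_B)
}

#' Significance of an observed Fowlkes-Mallows index
#'
#' Completes an [fm_index()] result with the null expectation, z statistic
#' and one-sided p-value under the null hypothesis of random assignment
#' (uniform relabeling of one partition, group sizes held fixed).
#'
#' Analytic mode uses the closed-form null moments of the pair-count
#' statistic (`E[Tk] = Pk Qk / (n(n-1))` and the matching variance) with a
#' normal approximation for p. Permutation mode relabels one partition
#' uniformly at random `n_perm` times, recomputes `B`, takes `expected_B`
#' and `z` from the empirical moments, and reports
#' `p = (1 + #\{B_perm >= B_obs\}) / (n_perm + 1)`. With `n <= 3` (or more
#' groups than the moment formulas tolerate) permutation mode is enforced.
#'
#' @param result An [fm_result][fm_index()] object.
#' @param mode `"analytic"` or `"permutation"`.
#' @param n_perm Number of permutations (>= 999) for permutation mode.
#' @param seed Integer seed for permutation mode.
#' @return The completed `fm_result`.
#' @export
fm_significance <- function(result, mode = c("analytic", "permutation"),
                            n_perm = 999, seed = 1L) {
  mode <- match.arg(mode)
  stopifnot(inherits(result, "fm_result"))
  n <- result$n
  if (n <= 3 && mode == "analytic") {
    inform("n <= 3: analytic null moments are degenerate, using permutation mode")
    mode <- "permutation"
  }

  if (mode == "analytic") {
    mom <- fm_analytic_moments(
      result$Pk, result$Qk, n,
      as.numeric(table(result$partition_a)),
      as.numeric(table(result$partition_b))
    )
    result$expected_B <- mom$expected_B
    sd_B <- sqrt(max(mom$var_B, 0))
    if (sd_B == 0) {
      stop_toxscreen("degenerate analytic null variance; use permutation mode",
                     "toxscreen_degenerate_error")
    }
    result$z <- (result$B - mom$expected_B) / sd_B
    result$p_value <- stats::pnorm(result$z, lower.tail = FALSE)
    result$null_mode <- "analytic"
  } else {
    if (n_perm < 999) {
      stop_toxscreen("permutation mode needs n_perm >= 999",
                     "toxscreen_input_error")
    }
    set.seed(as.integer(seed))
    a <- unname(result$partition_a)
    b <- unname(result$partition_b)
    ka <- max(a); kb <- max(b)
    # Pk and Qk are invariant under relabeling, so each permutation only
    # needs the contingency counts for Tk
    denom <- sqrt(result$Pk * result$Qk)
    perm_B <- vapply(seq_len(n_perm), function(i) {
      bp <- sample(b)
      tab <- tabulate((a - 1L) * kb + bp, nbins = ka * kb)
      (sum(tab^2) - n) / denom
    }, numeric(1))
    result$expected_B <- mean(perm_B)
    sd_B <- stats::sd(perm_B)
    result$z <- if (sd_B > 0) (result$B - result$expected_B) / sd_B else NA_real_
    result$p_value <- (1 + sum(perm_B >= result$B)) / (n_perm + 1)
    result$null_mode <- "permutation"
    result$n_permutations <- as.integer(n_perm)
  }
  result
}

#' @export
print.fm_result <- function(x, ...) {
  cat(sprintf("<fm_result> B = %.4f (n = %d; Tk = %d, Pk = %d, Qk = %d)\n",
              x$B, x$n, x$Tk, x$Pk, x$Qk))
  if (!is.na(x$null_mode)) {
    cat(sprintf("  null (%s): E[B] = %.4f, z = %.2f, one-sided p = %.4g\n",
                x$null_mode, x$expected_B, x$z, x$p_value))
  }
  invisible(x)
}
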