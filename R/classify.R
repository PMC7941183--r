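#' Build a repeated k-fold cross-validation scheme
#'
#' Assigns chemicals to folds for each repeat. Classes with at least `folds`
#' members are stratified (members dealt round-robin across folds after a
#' shuffle); smaller classes (e.g. a two-chemical class under 5 folds) are
#' assigned to distinct folds at random, which guarantees every class keeps
#' at least one training instance in every fold.
#'
#' @param classing Data frame with `chemical` and `class`.
#' @param folds Number of folds (default 5).
#' @param repeats Number of random repeats (default 50).
#' @param seed Master integer seed.
#' @return An object of class `cv_scheme`: `folds`, `repeats`, `seed`, and
#'   `assignments` (tibble `repeat_id`, `chemical`, `fold`).
#' @export
cv_scheme <- function(classing, folds = 5, repeats = 50, seed = 1L) {
  assert_columns(classing, c("chemical", "class"), "classing table")
  sizes <- table(classing$class)
  if (any(sizes < 2)) {
    stop_toxscreen(
      paste(
        "class(es) with a single member cannot be cross-validated:",
        paste(names(sizes)[sizes < 2], collapse = ", "),
        "- merge or drop them"
      ),
      "toxscreen_input_error"
    )
  }
  assignments <- purrr::map_dfr(seq_len(repeats), function(r) {
    set.seed(derive_seed(seed, c(5L, r)))
    purrr::map_dfr(split(classing$chemical, classing$class), function(members) {
      s <- length(members)
      fold <- if (s >= folds) {
        (sample(seq_len(s)) %% folds) + 1L
      } else {
        sample(seq_len(folds), s)
      }
      tibble::tibble(repeat_id = r, chemical = members, fold = as.integer(fold))
    })
  })
  structure(
    list(folds = as.integer(folds), repeats = as.integer(repeats),
         seed = as.integer(seed), assignments = assignments),
    class = "cv_scheme"
  )
}

check_features <- function(features, classing) {
  m <- feature_matrix_to_matrix(features)
  if (any(!is.finite(m))) {
    stop_toxscreen("feature matrix contains non-finite values",
                   "toxscreen_input_error")
  }
  missing <- setdiff(classing$chemical, rownames(m))
  if (length(missing) > 0) {
    stop_toxscreen(
      paste("chemical(s) missing from the feature matrix:",
            paste(utils::head(missing, 5), collapse = ", ")),
      "toxscreen_input_error"
    )
  }
  m[classing$chemical, , drop = FALSE]
}

# One train/predict pass; returns held-out predictions for one repeat.
predict_one_repeat <- function(m, y, assign_r, folds, ntree, seed_base) {
  purrr::map_dfr(seq_len(folds), function(f) {
    test_ids <- assign_r$chemical[assign_r$fold == f]
    if (length(test_ids) == 0) return(NULL)
    train_ids <- setdiff(rownames(m), test_ids)
    set.seed(derive_seed(seed_base, f))
    rf <- randomForest::randomForest(
      x = m[train_ids, , drop = FALSE],
      y = droplevels(y[train_ids]),
      ntree = ntree
    )
    pred <- stats::predict(rf, m[test_ids, , drop = FALSE])
    tibble::tibble(
      chemical = test_ids,
      true = as.character(y[test_ids]),
      predicted = as.character(pred)
    )
  })
}

#' Repeated cross-validated chemical-class prediction
#'
#' Trains a bagged, feature-subsampled decision-tree ensemble (random
#' forest, 500 trees, sqrt(p) features per split by default) to predict the
#' chemical class from a feature matrix, under the repeated k-fold scheme.
#' Predictions are made only on held-out folds; confusion counts are summed
#' over all repeats, so each chemical contributes `repeats` predictions.
#'
#' @param features Chemicals x features tibble or matrix (see
#'   [as_feature_matrix()]).
#' @param classing Data frame with `chemical` and `class`.
#' @param scheme A [cv_scheme()]; defaults to 5 folds x 50 repeats.
#' @param ntree Trees per forest.
#' @return An object of class `cv_classification`: `confusion` (true classes
#'   in rows, predicted in columns, summed over repeats), `accuracy` (%
#'   correct over all held-out predictions), `per_repeat_accuracy`,
#'   `predictions` (tibble `repeat_id`, `chemical`, `true`, `predicted`),
#'   `scheme`, `ntree`.
#' @export
repeated_cv_classify <- function(features, classing,
                                 scheme = cv_scheme(classing),
                                 ntree = 500) {
  m <- check_features(features, classing)
  y <- setNames(factor(classing$class), classing$chemical)

  predictions <- purrr::map_dfr(seq_len(scheme$repeats), function(r) {
    assign_r <- scheme$assignments[scheme$assignments$repeat_id == r, ]
    out <- predict_one_repeat(m, y, assign_r, scheme$folds, ntree,
                              derive_seed(scheme$seed, c(6L, r)))
    out$repeat_id <- r
    out
  })

  lev <- levels(y)
  confusion <- table(
    factor(predictions$true, levels = lev),
    factor(predictions$predicted, levels = lev),
    dnn = c("true", "predicted")
  )
  per_repeat <- predictions %>%
    dplyr::group_by(.data$repeat_id) %>%
    dplyr::summarise(acc = 100 * mean(.data$true == .data$predicted),
                     .groups = "drop")
  structure(
    list(
      confusion = unclass(confusion),
      accuracy = 100 * sum(diag(confusion)) / sum(confusion),
      per_repeat_accuracy = per_repeat$acc,
      predictions = predictions[, c("repeat_id", "chemical", "true", "predicted")],
      scheme = scheme, ntree = ntree
    ),
    class = "cv_classification"
  )
}

#' @export
print.cv_classification <- function(x, ...) {
  cat(sprintf("<cv_classification> accuracy %.1f%% over %d folds x %d repeats\n",
              x$accuracy, x$scheme$folds, x$scheme$repeats))
  print(x$confusion)
  invisible(x)
}

#' Permutation-null baseline for classification accuracy
#'
#' Re-runs the full repeated cross-validation after permuting the class
#' labels uniformly at random, `n_label_perms` times, to obtain the null
#' distribution of accuracy under no feature-class association, and reports
#' `p = (1 + #\{null >= observed\}) / (n_label_perms + 1)`.
#'
#' @inheritParams repeated_cv_classify
#' @param n_label_perms Number of label permutations (>= 99).
#' @param seed Integer seed for the permutations.
#' @return An object of class `cv_permutation`: `observed` (accuracy, %),
#'   `null_accuracy` (numeric vector), `p_value`, `n_label_perms`.
#' @export
permutation_baseline <- function(features, classing,
                                 scheme = cv_scheme(classing),
                                 n_label_perms = 99, seed = 1L,
                                 ntree = 500) {
  if (n_label_perms < 99) {
    stop_toxscreen("n_label_perms must be >= 99", "toxscreen_input_error")
  }
  observed <- repeated_cv_classify(features, classing, scheme, ntree)$accuracy
  null_acc <- vapply(seq_len(n_label_perms), function(i) {
    set.seed(derive_seed(seed, c(7L, i)))
    perm_classing <- classing
    perm_classing$class <- sample(classing$class)
    perm_scheme <- cv_scheme(perm_classing, scheme$folds, scheme$repeats,
                             derive_seed(seed, c(8L, i)))
    repeated_cv_classify(features, perm_classing, perm_scheme, ntree)$accuracy
  }, numeric(1))
  structure(
    list(
      observed = observed, null_accuracy = null_acc,
      p_value = (1 + sum(null_acc >= observed)) / (n_label_perms + 1),
      n_label_perms = as.integer(n_label_perms)
    ),
    class = "cv_permutation"
  )
}

#' @export
print.cv_permutation <- function(x, ...) {
  cat(sprintf(
    "<cv_permutation> observed %.1f%% vs null mean %.1f%% (p = %.4g, %d label permutations)\n",
    x$observed, mean(x$null_accuracy), x$p_value, x$n_label_perms
  ))
  invisible(x)
}

#' Held-out permutation feature importance
#'
#' For every feature, measures the mean decrease in held-out prediction
#' accuracy when that feature's values are shuffled within the test fold,
#' averaged over all folds and repeats. This is an out-of-sample,
#' model-agnostic importance: a feature the model never relies on scores 0.
#' Returns the top `k` features; ties broken by feature name.
#'
#' @inheritParams repeated_cv_classify
#' @param k Number of top features to return (clipped to the feature count
#'   with a warning).
#' @return A tibble of class `importance_table`: `feature`, `importance`
#'   (mean accuracy drop, percentage points), `rank`.
#' @export
feature_importance <- function(features, classing,
                               scheme = cv_scheme(classing),
                               ntree = 500, k = 10) {
  m <- check_features(features, classing)
  y <- setNames(factor(classing$class), classing$chemical)
  p <- ncol(m)
  if (k > p) {
    warn(sprintf("k = %d exceeds the %d available features; clipping", k, p))
    k <- p
  }

  drops <- matrix(0, nrow = p, ncol = 0)
  acc_drop <- rep(0, p)
  n_eval <- 0L
  for (r in seq_len(scheme$repeats)) {
    assign_r <- scheme$assignments[scheme$assignments$repeat_id == r, ]
    for (f in seq_len(scheme$folds)) {
      test_ids <- assign_r$chemical[assign_r$fold == f]
      if (length(test_ids) == 0) next
      train_ids <- setdiff(rownames(m), test_ids)
      set.seed(derive_seed(scheme$seed, c(9L, r, f)))
      rf <- randomForest::randomForest(
        x = m[train_ids, , drop = FALSE],
        y = droplevels(y[train_ids]),
        ntree = ntree
      )
      mt <- m[test_ids, , drop = FALSE]
      base_acc <- mean(stats::predict(rf, mt) == y[test_ids])
      perm_idx <- sample(nrow(mt))
      for (j in seq_len(p)) {
        mp <- mt
        mp[, j] <- mp[perm_idx, j]
        acc_drop[j] <- acc_drop[j] +
          (base_acc - mean(stats::predict(rf, mp) == y[test_ids]))
      }
      n_eval <- n_eval + 1L
    }
  }

  out <- tibble::tibble(
    feature = colnames(m),
    importance = 100 * acc_drop / n_eval
  ) %>%
    dplyr::arrange(dplyr::desc(.data$importance), .data$feature) %>%
    dplyr::mutate(rank = dplyr::row_number()) %>%
    dplyr::slice_head(n = k)
  structure(out, class = c("importance_table", class(out)))
}
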