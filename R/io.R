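screen_table_columns <- c(
  "chemical", "class", "cell_type", "phenotype", "category",
  "plate", "conc_uM", "replicate", "response_pct"
)

#' Read a long-format screen measurement table
#'
#' Reads the delimited exchange format written by [write_screen_table()]:
#' one row per well with columns `chemical`, `class`, `cell_type`,
#' `phenotype`, `category`, `plate`, `conc_uM` (micromolar; 0 for control
#' wells), `replicate`, `response_pct`. Rows with non-numeric concentration
#' or response are rejected individually, with their line numbers reported;
#' a file with no usable rows is an error, not an empty success.
#'
#' @param path Path to a comma-delimited text file with the documented
#'   header.
#' @return A tibble of well measurements.
#' @export
load_screen_table <- function(path) {
  if (!file.exists(path)) {
    stop_toxscreen(paste("no such file:", path), "toxscreen_input_error")
  }
  raw <- readr::read_csv(path, col_types = readr::cols(.default = "c"),
                         progress = FALSE)
  if (nrow(raw) == 0) {
    stop_toxscreen(paste("empty measurement table:", path),
                   "toxscreen_input_error")
  }
  assert_columns(raw, screen_table_columns, basename(path))

  conc <- suppressWarnings(as.numeric(raw$conc_uM))
  resp <- suppressWarnings(as.numeric(raw$response_pct))
  repl <- suppressWarnings(as.integer(raw$replicate))
  bad <- which(is.na(conc) | is.na(resp) | is.na(repl) | conc < 0)
  if (length(bad) > 0) {
    # +1 for the header: report file line numbers, not row indices
    inform(sprintf(
      "rejected %d malformed row(s) at file line(s): %s",
      length(bad),
      paste(utils::head(bad + 1, 10), collapse = ", ")
    ))
  }
  keep <- setdiff(seq_len(nrow(raw)), bad)
  if (length(keep) == 0) {
    stop_toxscreen("no valid measurement rows after rejection",
                   "toxscreen_input_error")
  }
  tibble::tibble(
    chemical = raw$chemical[keep],
    class = raw$class[keep],
    cell_type = raw$cell_type[keep],
    phenotype = raw$phenotype[keep],
    category = raw$category[keep],
    plate = raw$plate[keep],
    conc_uM = conc[keep],
    replicate = repl[keep],
    response_pct = resp[keep]
  )
}

#' Write a screen measurement table (and optionally its ground truth)
#'
#' @param screen A [simulate_screen()] result or a measurement tibble.
#' @param path Output CSV path for the measurements.
#' @param truth_path Optional CSV path for the true-curve table (only
#'   written for synthetic screens).
#' @return `path`, invisibly.
#' @export
write_screen_table <- function(screen, path, truth_path = NULL) {
  meas <- if (inherits(screen, "synthetic_screen")) screen$measurements else screen
  assert_columns(meas, screen_table_columns, "measurement table")
  readr::write_csv(meas[, screen_table_columns], path, progress = FALSE)
  if (!is.null(truth_path) && inherits(screen, "synthetic_screen")) {
    readr::write_csv(screen$truth, truth_path, progress = FALSE)
  }
  invisible(path)
}

#' Assemble a pipeline run configuration
#'
#' @param measurements Path to a measurement CSV, or an in-memory
#'   measurement tibble / [simulate_screen()] result.
#' @param classing Optional chemical-to-class table (tibble or CSV path);
#'   without it the grouping stage runs unsupervised-only and
#'   classification is skipped.
#' @param tk_table Optional toxicokinetic/exposure table (tibble or CSV
#'   path); without it the risk stage is skipped.
#' @param scale_mode,distance,linkage,k,folds,repeats,ntree,moe_benchmark,qc_thresholds
#'   Stage parameters (see the stage functions).
#' @param seed Master seed for every stochastic stage.
#' @param output_dir Directory for the output tables and run manifest
#'   (`NULL` = do not write files).
#' @return A list of class `run_config`.
#' @export
run_config <- function(measurements,
                       classing = NULL,
                       tk_table = NULL,
                       scale_mode = "log10",
                       distance = "pearson",
                       linkage = "average",
                       k = NULL,
                       folds = 5,
                       repeats = 50,
                       ntree = 500,
                       moe_benchmark = 100,
                       qc_thresholds = list(),
                       seed = 1L,
                       output_dir = NULL) {
  load_maybe <- function(x, loader) {
    if (is.character(x)) {
      if (!file.exists(x)) {
        stop_toxscreen(paste("no such file:", x), "toxscreen_input_error")
      }
      loader(x)
    } else x
  }
  structure(
    list(
      measurements = load_maybe(measurements, load_screen_table),
      classing = load_maybe(
        classing,
        function(p) readr::read_csv(p, show_col_types = FALSE, progress = FALSE)
      ),
      tk_table = load_maybe(
        tk_table,
        function(p) readr::read_csv(p, show_col_types = FALSE, progress = FALSE)
      ),
      scale_mode = scale_mode, distance = distance, linkage = linkage,
      k = k, folds = folds, repeats = repeats, ntree = ntree,
      moe_benchmark = moe_benchmark, qc_thresholds = qc_thresholds,
      seed = as.integer(seed), output_dir = output_dir
    ),
    class = "run_config"
  )
}

#' Run the full hazard-characterization pipeline
#'
#' Chains every stage: vehicle normalization, assay QC, Hill fitting and POD
#' derivation, functional-vs-cytotoxicity contrast, ToxPi scaling /
#' aggregation / class ranges, hierarchical grouping scored against the
#' reference classing by the Fowlkes-Mallows index (with permutation
#' significance), repeated cross-validated class prediction with held-out
#' feature importance, and the margin-of-exposure screen. Stages whose
#' inputs are absent are skipped with a notice (no classing: FM scoring and
#' classification are skipped; no toxicokinetic table: the risk stage is
#' skipped). With an `output_dir` every stage's table is written as CSV
#' together with a machine-readable JSON run manifest (configuration, seed,
#' package version, row counts) sufficient to reproduce the run.
#'
#' @param config A [run_config()].
#' @return A list of class `toxscreen_results` with elements
#'   `vehicle_stats`, `qc_report`, `pod_table`, `category_contrast`,
#'   `toxpi_scores`, `toxpi_profiles`, `class_ranges`, `clustering`,
#'   `fm`, `classification`, `importance`, `moe`, `manifest`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  meas <- if (inherits(config$measurements, "synthetic_screen")) {
    config$measurements$measurements
  } else {
    config$measurements
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop_toxscreen(
        sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
        "toxscreen_stage_error"
      )
    })
  }

  normalized <- stage("normalize", normalize_to_vehicle(meas))
  qc <- stage("qc", qc_assay(meas, thresholds = config$qc_thresholds))
  pods <- stage("pod", fit_pod_table(normalized))
  contrast <- stage("contrast", phenotype_category_contrast(pods))
  scores <- stage("toxpi", scale_pod_matrix(pods, config$scale_mode))
  profiles <- stage("toxpi", toxpi_profile(scores))
  features <- stage("features", as_feature_matrix(scores))

  classing <- config$classing
  has_classing <- !is.null(classing)
  k <- config$k %||%
    (if (has_classing) length(unique(classing$class)) else 5L)

  clustering <- stage(
    "grouping",
    cluster_chemicals(features, k = k, distance = config$distance,
                      linkage = config$linkage)
  )

  class_ranges <- NULL; fm <- NULL; cls <- NULL; imp <- NULL
  if (has_classing) {
    class_ranges <- stage("toxpi", class_score_ranges(profiles, classing))
    fm <- stage("grouping", {
      fm_index(clustering, classing[, c("chemical", "class")]) %>%
        fm_significance(mode = "permutation", n_perm = 999,
                        seed = derive_seed(config$seed, 11L))
    })
    scheme <- cv_scheme(classing, folds = config$folds,
                        repeats = config$repeats, seed = config$seed)
    cls <- stage("classify",
                 repeated_cv_classify(features, classing, scheme, config$ntree))
    imp <- stage("classify",
                 feature_importance(features, classing, scheme, config$ntree))
  } else {
    inform("no classing supplied: FM scoring and classification skipped")
  }

  moe <- NULL
  if (!is.null(config$tk_table)) {
    moe <- stage("risk", moe_screen(pods, config$tk_table,
                                    benchmark = config$moe_benchmark))
  } else {
    inform("no toxicokinetic table supplied: risk stage skipped")
  }

  manifest <- list(
    package = "toxscreen",
    version = as.character(utils::packageVersion("toxscreen")),
    seed = config$seed,
    parameters = config[c("scale_mode", "distance", "linkage", "folds",
                          "repeats", "ntree", "moe_benchmark")],
    k = k,
    counts = list(
      wells = nrow(meas),
      chemicals = length(unique(pods$chemical)),
      phenotypes = length(unique(pods$phenotype)),
      pods_censored = sum(pods$censored),
      moe_chemicals = if (is.null(moe)) 0L else nrow(moe)
    )
  )

  results <- structure(
    list(
      vehicle_stats = normalized$vehicle_stats, qc_report = qc,
      pod_table = pods, category_contrast = contrast,
      toxpi_scores = scores, toxpi_profiles = profiles,
      class_ranges = class_ranges, clustering = clustering, fm = fm,
      classification = cls, importance = imp, moe = moe,
      manifest = manifest
    ),
    class = "toxscreen_results"
  )

  if (!is.null(config$output_dir)) {
    write_results(results, config$output_dir)
  }
  results
}

write_results <- function(results, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  w <- function(df, name) {
    if (!is.null(df)) {
      readr::write_csv(tibble::as_tibble(df), file.path(dir, name),
                       progress = FALSE)
    }
  }
  w(results$pod_table, "pod_table.csv")
  w(results$qc_report, "qc_report.csv")
  w(results$toxpi_profiles, "toxpi_profiles.csv")
  w(results$class_ranges, "class_score_ranges.csv")
  w(results$clustering$partition, "cluster_partition.csv")
  if (!is.null(results$fm)) {
    w(tidy(results$fm), "fm_index.csv")
  }
  if (!is.null(results$classification)) {
    w(tidy(results$classification), "classification_confusion.csv")
    w(results$importance, "feature_importance.csv")
  }
  w(results$moe, "moe_table.csv")
  jsonlite::write_json(results$manifest, file.path(dir, "run_manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(dir)
}

#' @export
print.toxscreen_results <- function(x, ...) {
  cat("<toxscreen_results>\n")
  cat("  PODs:", nrow(x$pod_table),
      sprintf("(%d censored)", sum(x$pod_table$censored)), "\n")
  if (!is.null(x$fm)) {
    cat(sprintf("  FM vs reference classing: %.3f (p = %.4g)\n",
                x$fm$B, x$fm$p_value))
  }
  if (!is.null(x$classification)) {
    cat(sprintf("  CV class-prediction accuracy: %.1f%%\n",
                x$classification$accuracy))
  }
  if (!is.null(x$moe)) {
    cat(sprintf("  MoE: %d / %d chemicals of potential concern\n",
                attr(x$moe, "n_concern"), attr(x$moe, "n_total")))
  }
  invisible(x)
}
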