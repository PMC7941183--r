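#' Reference chemical-to-class annotation (42 ATSDR priority chemicals)
#'
#' Returns the packaged annotation table of 42 Superfund-priority chemicals
#' grouped into five ATSDR classes (inorganic substances, PAHs, pesticides,
#' other industrial chemicals, phthalates). This classing is the reference
#' ("ground truth") partition against which unsupervised grouping is scored
#' and on which class-prediction models are trained.
#'
#' @return A tibble with columns `chemical`, `class`, `cas`, `atsdr_rank`.
#' @export
#' @examples
#' atsdr_chemicals() %>% dplyr::count(class)
atsdr_chemicals <- function() {
  path <- system.file("extdata", "atsdr_chemicals.csv", package = "toxscreen")
  readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
}

# Table of assay phenotypes per cell type. Phenotype ids are prefixed with
# the cell type so they are unique across the whole screen (the POD table is
# chemicals x phenotypes).
default_phenotypes <- function() {
  ph <- list(
    hepatocyte = list(
      functional = c("mitochondrial_integrity", "mitochondrial_intensity"),
      cytotoxicity = c("cell_number", "nuclei_intensity", "all_cell_mean_area")
    ),
    neuron = list(
      functional = c(
        "total_outgrowth", "mean_outgrowth", "total_process",
        "total_branches", "cells_significant_growth"
      ),
      cytotoxicity = c(
        "cell_number", "mitochondrial_integrity", "cytoplasmic_integrity",
        "total_cell_body_area", "atp"
      )
    ),
    cardiomyocyte = list(
      functional = c(
        "beats_per_minute", "peak_amplitude", "peak_spacing", "peak_width",
        "peak_rise_time", "peak_decay_time", "decay_rise_ratio"
      ),
      cytotoxicity = c("cell_number", "mitochondrial_integrity")
    ),
    endothelial = list(
      functional = c("total_tube_length", "mean_tube_length", "total_tube_area"),
      cytotoxicity = c(
        "cell_number", "mitochondrial_integrity", "mitochondrial_intensity",
        "cytoplasmic_integrity", "nuclei_mean_area"
      )
    ),
    huvec = list(
      functional = c("total_tube_length", "mean_tube_length", "total_tube_area"),
      cytotoxicity = c(
        "cell_number", "mitochondrial_integrity", "mitochondrial_intensity",
        "cytoplasmic_integrity", "nuclei_mean_area", "atp"
      )
    )
  )
  purrr::imap_dfr(ph, function(cats, ct) {
    purrr::imap_dfr(cats, function(names, cat) {
      tibble::tibble(
        cell_type = ct,
        phenotype = paste(ct, names, sep = ":"),
        category = cat
      )
    })
  })
}

#' Define a screening-plate design
#'
#' Describes the layout of a multi-cell-type concentration-response screen:
#' which chemicals (with their class labels), which cell types and phenotypes,
#' the concentration series, and replication. Defaults reproduce the
#' five-cell-type screen: 42 chemicals in 5 classes, 41 phenotypes across
#' hepatocytes, neurons, cardiomyocytes, iPSC-derived endothelial cells and
#' HUVECs, a five-point log-spaced series (100, 10, 1, 0.1, 0.01 uM), three
#' treated replicates, and 16 vehicle-control plus 16 medium-control wells
#' per plate and phenotype.
#'
#' @param chemicals Data frame with columns `chemical` and `class`.
#'   Defaults to [atsdr_chemicals()].
#' @param phenotypes Data frame with columns `cell_type`, `phenotype`,
#'   `category` (`"functional"` or `"cytotoxicity"`). Defaults to the packaged
#'   41-phenotype layout.
#' @param conc_uM Strictly decreasing concentration series in micromolar.
#' @param n_replicates Treated replicates per concentration.
#' @param n_vehicle_wells Vehicle-control (solvent-only) wells per plate and
#'   phenotype; must be at least 2.
#' @param n_medium_wells Medium-only negative-control wells per plate and
#'   phenotype (0 disables the second negative control).
#' @return An object of class `screen_design`.
#' @export
screen_design <- function(chemicals = atsdr_chemicals(),
                          phenotypes = default_phenotypes(),
                          conc_uM = c(100, 10, 1, 0.1, 0.01),
                          n_replicates = 3,
                          n_vehicle_wells = 16,
                          n_medium_wells = 16) {
  chemicals <- tibble::as_tibble(chemicals)
  phenotypes <- tibble::as_tibble(phenotypes)
  assert_columns(chemicals, c("chemical", "class"), "chemicals table")
  assert_columns(phenotypes, c("cell_type", "phenotype", "category"), "phenotypes table")
  if (nrow(chemicals) == 0 || nrow(phenotypes) == 0) {
    stop_toxscreen("screen design needs at least one chemical and one phenotype",
                   "toxscreen_config_error")
  }
  if (anyDuplicated(chemicals$chemical)) {
    stop_toxscreen("duplicate chemical ids in design", "toxscreen_input_error")
  }
  if (anyDuplicated(phenotypes$phenotype)) {
    stop_toxscreen("duplicate phenotype ids in design", "toxscreen_input_error")
  }
  if (length(conc_uM) < 1 || any(diff(conc_uM) >= 0) || any(conc_uM <= 0)) {
    stop_toxscreen("conc_uM must be a strictly decreasing positive series",
                   "toxscreen_config_error")
  }
  if (n_vehicle_wells < 2) {
    stop_toxscreen("at least 2 vehicle wells per plate are required",
                   "toxscreen_config_error")
  }
  structure(
    list(
      chemicals = chemicals,
      phenotypes = phenotypes,
      cell_types = unique(phenotypes$cell_type),
      conc_uM = conc_uM,
      n_replicates = as.integer(n_replicates),
      n_vehicle_wells = as.integer(n_vehicle_wells),
      n_medium_wells = as.integer(n_medium_wells)
    ),
    class = "screen_design"
  )
}

#' @export
print.screen_design <- function(x, ...) {
  cat("<screen_design>\n")
  cat("  chemicals: ", nrow(x$chemicals), " in ",
      length(unique(x$chemicals$class)), " classes\n", sep = "")
  cat("  phenotypes:", nrow(x$phenotypes), "across", length(x$cell_types),
      "cell types\n")
  cat("  concentrations (uM):", paste(x$conc_uM, collapse = ", "), "\n")
  cat("  replicates:", x$n_replicates,
      "| vehicle wells:", x$n_vehicle_wells,
      "| medium wells:", x$n_medium_wells, "\n")
  invisible(x)
}

#' Default class-by-cell-type potency profiles
#'
#' One row per (class, cell type) describing how member chemicals of that
#' class behave in that cell type: the location (`mean_log10_ec50`) and
#' spread (`sd_log10_ec50`) of log10 EC50 (uM) for active phenotypes, the
#' fraction of phenotypes expected to respond at all (`activity_prob`), and
#' the chance a responding phenotype decreases rather than increases
#' (`direction_prob`). The defaults plant well-separated class signatures
#' mirroring the qualitative structure seen in screens of this kind:
#' inorganic substances broadly potent in every cell type, pesticides
#' selectively potent in cardiomyocytes, PAHs moderately active in
#' hepatocytes and neurons, other industrial chemicals mostly affecting
#' iPSC-derived endothelial cells, and phthalates mostly affecting HUVECs.
#'
#' @param cell_types Character vector of cell types to cover.
#' @return A tibble with columns `class`, `cell_type`, `mean_log10_ec50`,
#'   `sd_log10_ec50`, `activity_prob`, `direction_prob`.
#' @export
class_potency_profiles <- function(cell_types = unique(default_phenotypes()$cell_type)) {
  base <- list(
    # broadly potent in every cell type, with a graded potency pattern
    # (strongest in hepatocytes/neurons) so class members share profile shape
    "Inorganic substances" = list(
      hepatocyte = c(mean = -2.0, sd = 0.2, act = 1.0, dir = 0.85),
      neuron = c(mean = -1.2, sd = 0.2, act = 1.0, dir = 0.85),
      endothelial = c(mean = -0.6, sd = 0.2, act = 1.0, dir = 0.85),
      huvec = c(mean = 0.2, sd = 0.2, act = 1.0, dir = 0.85),
      cardiomyocyte = c(mean = 0.8, sd = 0.2, act = 1.0, dir = 0.85)
    ),
    "Pesticides" = list(
      cardiomyocyte = c(mean = -1.0, sd = 0.3, act = 0.95, dir = 0.85),
      default = c(mean = 2.0, sd = 0.3, act = 0.05, dir = 0.70)
    ),
    "PAHs" = list(
      hepatocyte = c(mean = 0.0, sd = 0.3, act = 0.90, dir = 0.80),
      neuron = c(mean = -0.5, sd = 0.3, act = 0.90, dir = 0.80),
      default = c(mean = 2.0, sd = 0.3, act = 0.05, dir = 0.70)
    ),
    "Other industrial chemicals" = list(
      endothelial = c(mean = -0.5, sd = 0.3, act = 0.90, dir = 0.80),
      default = c(mean = 2.0, sd = 0.3, act = 0.05, dir = 0.70)
    ),
    "Phthalates" = list(
      huvec = c(mean = -0.5, sd = 0.3, act = 0.90, dir = 0.80),
      default = c(mean = 2.0, sd = 0.3, act = 0.05, dir = 0.70)
    )
  )
  purrr::imap_dfr(base, function(spec, cls) {
    purrr::map_dfr(cell_types, function(ct) {
      p <- spec[[ct]] %||% spec$default
      tibble::tibble(
        class = cls, cell_type = ct,
        mean_log10_ec50 = unname(p["mean"]),
        sd_log10_ec50 = unname(p["sd"]),
        activity_prob = unname(p["act"]),
        direction_prob = unname(p["dir"])
      )
    })
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

validate_profiles <- function(profiles, design) {
  assert_columns(
    profiles,
    c("class", "cell_type", "mean_log10_ec50", "sd_log10_ec50",
      "activity_prob", "direction_prob"),
    "potency profiles"
  )
  if (any(profiles$activity_prob < 0 | profiles$activity_prob > 1)) {
    stop_toxscreen("activity_prob must lie in [0, 1]", "toxscreen_input_error")
  }
  if (any(profiles$sd_log10_ec50 < 0)) {
    stop_toxscreen("sd_log10_ec50 must be >= 0", "toxscreen_input_error")
  }
  bad_ct <- setdiff(profiles$cell_type, design$cell_types)
  if (length(bad_ct) > 0) {
    stop_toxscreen(
      paste("profile references unknown cell type(s):", paste(bad_ct, collapse = ", ")),
      "toxscreen_input_error"
    )
  }
  need <- tidyr::expand_grid(
    class = unique(design$chemicals$class),
    cell_type = design$cell_types
  )
  have <- dplyr::semi_join(need, profiles, by = c("class", "cell_type"))
  if (nrow(have) < nrow(need)) {
    stop_toxscreen("potency profiles must cover every class x cell type in the design",
                   "toxscreen_config_error")
  }
  invisible(profiles)
}
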