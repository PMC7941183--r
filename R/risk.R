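#' Per-chemical surrogate POD (most sensitive phenotype)
#'
#' Collapses a POD table to one surrogate POD per chemical: the minimum POD
#' over the phenotypes in scope -- either one cell type or all cell types
#' combined. Censoring propagates: a chemical whose in-scope PODs are all
#' censored at the maximum tested concentration gets a censored surrogate at
#' that bound, flagged, which downstream margin-of-exposure treats as a
#' lower bound.
#'
#' @param pods A [fit_pod_table()] result.
#' @param scope `"all"` or a single cell-type name.
#' @return A tibble: `chemical`, `scope`, `pod` (uM), `censored`.
#' @export
surrogate_pod <- function(pods, scope = "all") {
  assert_columns(pods, c("chemical", "cell_type", "pod", "censored"), "POD table")
  if (!"censor_side" %in% names(pods)) {
    pods$censor_side <- ifelse(pods$censored, "high", NA_character_)
  }
  df <- if (identical(scope, "all")) pods else pods[pods$cell_type == scope, ]
  if (nrow(df) == 0) {
    stop_toxscreen(sprintf("no phenotypes in scope '%s'", scope),
                   "toxscreen_input_error")
  }
  df %>%
    dplyr::group_by(.data$chemical) %>%
    dplyr::summarise(
      scope = scope,
      # high-censored PODs are "no observed crossing"; the surrogate is the
      # minimum over the rest, else the censoring bound itself
      pod = if (all(.data$censored & .data$censor_side == "high")) {
        min(.data$pod)
      } else {
        min(.data$pod[!(.data$censored & .data$censor_side == "high")])
      },
      censored = all(.data$censored & .data$censor_side == "high"),
      .groups = "drop"
    )
}

#' Convert a micromolar POD to an administered equivalent dose
#'
#' Under the linear dose-to-steady-state assumption, a chemical with
#' steady-state plasma concentration `css_per_unit_dose` (uM per 1 mg/kg/day
#' of oral dose, typically an upper-95th-percentile toxicokinetic-variability
#' value) reaches an in vitro concentration `pod_uM` at the administered
#' equivalent dose `AED = pod_uM / css_per_unit_dose` (mg/kg/day).
#'
#' @param pod_uM POD(s) in uM.
#' @param css_per_unit_dose Steady-state concentration per unit dose, uM per
#'   mg/kg/day (> 0).
#' @return AED in mg/kg/day, vectorized.
#' @seealso [dose_to_css()] for the inverse conversion.
#' @export
pod_to_aed <- function(pod_uM, css_per_unit_dose) {
  if (any(!is.na(css_per_unit_dose) & css_per_unit_dose <= 0)) {
    stop_toxscreen("css_per_unit_dose must be > 0", "toxscreen_input_error")
  }
  pod_uM / css_per_unit_dose
}

#' Convert an oral dose to a steady-state concentration
#'
#' Inverse of [pod_to_aed()]: `Css = dose x css_per_unit_dose` (uM).
#'
#' @param dose Oral dose(s), mg/kg/day.
#' @inheritParams pod_to_aed
#' @export
dose_to_css <- function(dose, css_per_unit_dose) {
  if (any(!is.na(css_per_unit_dose) & css_per_unit_dose <= 0)) {
    stop_toxscreen("css_per_unit_dose must be > 0", "toxscreen_input_error")
  }
  dose * css_per_unit_dose
}

#' Compare NAM-based PODs to in vivo regulatory PODs
#'
#' Pairs dose-scale NAM PODs with in vivo PODs (the values underlying
#' regulatory reference doses) and summarizes conservatism: the per-chemical
#' `log10(NAM / in vivo)` ratio, the fraction of chemicals where the NAM POD
#' is strictly higher than the in vivo POD ("unconservative"), and the
#' fraction of those unconservative cases still within 10-fold of the in
#' vivo value. Units are declared, never guessed: both inputs must be in
#' mg/kg/day.
#'
#' @param nam_pods Tibble with `chemical` and `pod_aed` (mg/kg/day).
#' @param invivo_pods Tibble with `chemical` and `pod_rfd` (mg/kg/day).
#' @param nam_units,invivo_units Declared units; must both be
#'   `"mg/kg/day"`.
#' @return A list of class `conservatism_result`: `ratios` (tibble
#'   `chemical`, `pod_aed`, `pod_rfd`, `log10_ratio`, `unconservative`),
#'   `n`, `frac_unconservative`, `frac_unconservative_within_10x`.
#' @export
conservatism_comparison <- function(nam_pods, invivo_pods,
                                    nam_units = "mg/kg/day",
                                    invivo_units = "mg/kg/day") {
  if (!identical(nam_units, invivo_units) || !identical(nam_units, "mg/kg/day")) {
    stop_toxscreen(
      sprintf("unit mismatch: NAM PODs in '%s', in vivo PODs in '%s'; both must be mg/kg/day",
              nam_units, invivo_units),
      "toxscreen_unit_error"
    )
  }
  assert_columns(nam_pods, c("chemical", "pod_aed"), "NAM POD table")
  assert_columns(invivo_pods, c("chemical", "pod_rfd"), "in vivo POD table")
  ratios <- dplyr::inner_join(
    nam_pods[, c("chemical", "pod_aed")],
    invivo_pods[, c("chemical", "pod_rfd")],
    by = "chemical"
  ) %>%
    dplyr::filter(is.finite(.data$pod_aed), is.finite(.data$pod_rfd)) %>%
    dplyr::mutate(
      log10_ratio = log10(.data$pod_aed / .data$pod_rfd),
      unconservative = .data$pod_aed > .data$pod_rfd
    )
  if (nrow(ratios) == 0) {
    stop_toxscreen("no chemicals shared between the NAM and in vivo POD tables",
                   "toxscreen_input_error")
  }
  n_unc <- sum(ratios$unconservative)
  structure(
    list(
      ratios = ratios,
      n = nrow(ratios),
      frac_unconservative = n_unc / nrow(ratios),
      frac_unconservative_within_10x = if (n_unc == 0) NA_real_ else {
        sum(ratios$unconservative & ratios$log10_ratio <= 1) / n_unc
      }
    ),
    class = "conservatism_result"
  )
}

#' @export
print.conservatism_result <- function(x, ...) {
  cat(sprintf(
    "<conservatism_result> n = %d; %.0f%% unconservative (NAM > in vivo)",
    x$n, 100 * x$frac_unconservative
  ))
  if (!is.na(x$frac_unconservative_within_10x)) {
    cat(sprintf(", of which %.0f%% within 10-fold",
                100 * x$frac_unconservative_within_10x))
  }
  cat("\n")
  invisible(x)
}

#' Margin-of-exposure screen
#'
#' Computes `MoE = pod_aed / exposure` per chemical and flags "potential
#' concern" when the MoE is strictly below the benchmark (default 100; an
#' MoE of exactly 100 is not flagged). Zero exposure yields an infinite,
#' unflagged MoE. When the dose-scale POD came from a censored surrogate the
#' MoE is only a lower bound; in conservative mode (default) such bounds are
#' still flagged when below the benchmark, otherwise they are left unflagged.
#'
#' @param records Tibble with `chemical`, `pod_aed` (mg/kg/day), `exposure`
#'   (mg/kg/day, >= 0), and optionally `censored` (surrogate POD censoring).
#' @param benchmark MoE concern threshold (default 100).
#' @param conservative Flag censored lower bounds below the benchmark?
#' @return A tibble of class `moe_table`: `chemical`, `pod_aed`, `exposure`,
#'   `moe`, `moe_is_lower_bound`, `concern`; the number flagged out of the
#'   total is in the `n_concern` / `n_total` attributes.
#' @export
margin_of_exposure <- function(records, benchmark = 100, conservative = TRUE) {
  assert_columns(records, c("chemical", "pod_aed", "exposure"), "MoE records")
  if (any(records$exposure < 0, na.rm = TRUE)) {
    stop_toxscreen("exposure must be >= 0", "toxscreen_input_error")
  }
  if (!"censored" %in% names(records)) records$censored <- FALSE
  out <- records %>%
    dplyr::mutate(
      moe = ifelse(.data$exposure == 0, Inf, .data$pod_aed / .data$exposure),
      moe_is_lower_bound = .data$censored,
      concern = dplyr::case_when(
        !is.finite(.data$moe) ~ FALSE,
        .data$censored & !conservative ~ FALSE,
        TRUE ~ .data$moe < benchmark
      )
    ) %>%
    dplyr::select("chemical", "pod_aed", "exposure", "moe",
                  "moe_is_lower_bound", "concern")
  structure(out, class = c("moe_table", class(out)),
            n_concern = sum(out$concern), n_total = nrow(out),
            benchmark = benchmark)
}

#' End-to-end margin-of-exposure screen from a POD table
#'
#' Chains [surrogate_pod()], [pod_to_aed()] and [margin_of_exposure()]:
#' collapses the POD table to per-chemical surrogate PODs in the requested
#' scope, converts them to administered equivalent doses with the supplied
#' toxicokinetic factors, and screens against the exposure estimates.
#' Chemicals without a toxicokinetic factor or exposure estimate are dropped
#' with a message (pairwise exclusion).
#'
#' @param pods A [fit_pod_table()] result.
#' @param tk_table Tibble with `chemical`, `css_per_unit_dose` (uM per
#'   mg/kg/day), `exposure` (mg/kg/day); extra columns pass through.
#' @inheritParams surrogate_pod
#' @inheritParams margin_of_exposure
#' @return A [margin_of_exposure()] result.
#' @export
moe_screen <- function(pods, tk_table, scope = "all", benchmark = 100,
                       conservative = TRUE) {
  assert_columns(tk_table, c("chemical", "css_per_unit_dose", "exposure"),
                 "toxicokinetic table")
  sur <- surrogate_pod(pods, scope)
  merged <- dplyr::inner_join(sur, tk_table, by = "chemical")
  dropped <- nrow(sur) - nrow(merged)
  if (dropped > 0) {
    inform(sprintf(
      "%d chemical(s) without toxicokinetic/exposure data dropped from the MoE screen",
      dropped
    ))
  }
  merged$pod_aed <- pod_to_aed(merged$pod, merged$css_per_unit_dose)
  margin_of_exposure(merged, benchmark = benchmark, conservative = conservative)
}

#' Synthetic toxicokinetic and exposure fixture
#'
#' A packaged toy table of per-chemical steady-state-concentration factors,
#' exposure estimates and in vivo PODs for a 16-chemical subset of the
#' reference classing. The values are synthetic (order-of-magnitude
#' plausible, not measured); they exist so the risk stage can be exercised
#' and tested without external toxicokinetic databases.
#'
#' @return A tibble: `chemical`, `css_per_unit_dose` (uM per mg/kg/day,
#'   upper-95th-percentile style factor), `exposure` (mg/kg/day),
#'   `pod_rfd` (mg/kg/day).
#' @export
synthetic_tk_table <- function() {
  path <- system.file("extdata", "tk_exposure_synthetic.csv",
                      package = "toxscreen")
  readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
}
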