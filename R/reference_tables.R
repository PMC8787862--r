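#' Published reference estimates from the multicenter prostate IMRT study
#'
#' The package defaults are calibrated against a French prospective
#' multicenter study of high-risk prostate cancer with pelvic nodal
#' irradiation that compared volumetric modulated arc therapy (VMAT,
#' n = 106) with helical tomotherapy (HT, n = 49) using micro-costing and
#' stabilized inverse-probability-of-treatment weighting. These accessors
#' return the study's published arm-level summaries (2019 euros), which
#' serve two purposes: they are the calibration targets of
#' [default_cohort_config()] / [default_unit_costs()], and they are the
#' inputs of arithmetic consistency checks (component sums, cost shares)
#' that do not require patient-level data.
#'
#' @return `reference_cost_summary()`: a tibble with one row per cost
#'   component and arm, columns `component`, `arm`, `mean`, `sd`
#'   (euros per patient, IPTW-weighted means).
#' @examples
#' reference_cost_summary()
#' @export
reference_cost_summary <- function() {
  comp <- cost_components()
  tibble::tibble(
    component = rep(comp, each = 2L),
    arm = rep(c("VMAT", "HT"), times = length(comp)),
    mean = c(
      109.10,   38.75,   # image_registration_labor
       95.98,    0.00,   # image_registration_tps
      141.47,   67.49,   # inverse_planning_labor
      133.48,    0.00,   # inverse_planning_tps
       19.96,   24.00,   # patient_qc_labor
       22.94,   12.21,   # setup_d0_labor
       43.27,   46.19,   # setup_d0_accelerator
      484.52,  546.84,   # session_labor
     1493.66, 2333.30),  # session_accelerator
    sd = c(
       76.47,   56.59,
       65.79,    0.00,
      104.02,   66.39,
       90.17,    0.00,
       12.12,   10.43,
       30.40,    7.66,
       56.24,   25.85,
      135.28,  120.39,
      362.39,  466.52)
  )
}

#' @rdname reference_cost_summary
#' @return `reference_baseline()`: a tibble of baseline covariate summaries
#'   per arm (counts for categorical levels, mean/SD for continuous
#'   covariates) from the unweighted study population.
#' @export
reference_baseline <- function() {
  tibble::tibble(
    covariate = c("age", "age",
                  "performance_status", "performance_status",
                  "c_t_stage", "c_t_stage", "c_t_stage", "c_t_stage",
                  "c_n_stage", "c_n_stage",
                  "psa", "psa"),
    level = c("mean", "sd", "0", "1-2", "cT1", "cT2", "cT3", "cT4",
              "cN0", "cN1", "mean", "sd"),
    vmat = c(68, 7, 93, 13, 14, 35, 55, 2, 96, 10, 15, 13),
    ht   = c(70, 9, 38, 11,  9, 10, 27, 3, 38, 11, 18, 13)
  )
}

#' @rdname reference_cost_summary
#' @return `reference_toxicity()`: a tibble of collapsed CTCAE grade counts
#'   per endpoint, window and arm (unweighted; toxicity follow-up was
#'   available for 98 of the 106 VMAT patients and all 49 HT patients).
#' @export
reference_toxicity <- function() {
  g <- rep(.GRADES, times = 6L)
  tibble::tibble(
    window = rep(c("acute", "late"), each = 12L),
    endpoint = rep(rep(.ENDPOINTS, each = 4L), times = 2L),
    grade = g,
    vmat = c(17, 48, 32, 1,   10, 34, 50, 4,   49, 21, 27, 1,
             41, 38, 18, 1,   26, 50, 20, 2,   38, 19, 37, 4),
    ht   = c(14, 26,  9, 0,    7, 24, 16, 2,   33,  1, 15, 0,
             27, 13,  7, 2,   14, 20, 14, 1,   15,  1, 33, 0)
  )
}
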