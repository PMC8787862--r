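# phase -> labor component; phase x equipment -> equipment component
.LABOR_COMPONENT <- c(
  image_registration_contouring = "image_registration_labor",
  inverse_planning = "inverse_planning_labor",
  patient_qc = "patient_qc_labor",
  setup_verification_d0 = "setup_d0_labor",
  session = "session_labor")

.EQUIP_COMPONENT <- c(
  "image_registration_contouring.TPS" = "image_registration_tps",
  "inverse_planning.TPS" = "inverse_planning_tps",
  "setup_verification_d0.accelerator" = "setup_d0_accelerator",
  "session.accelerator" = "session_accelerator")

.PLANNING_COMPONENTS <- c("image_registration_labor", "image_registration_tps",
                          "inverse_planning_labor", "inverse_planning_tps",
                          "patient_qc_labor", "setup_d0_labor",
                          "setup_d0_accelerator")
.SESSION_COMPONENTS <- c("session_labor", "session_accelerator")

#' Per-patient cost breakdowns for a cohort
#'
#' Values every resource-use event at the unit costs and aggregates to the
#' nine-component per-patient breakdown. Labor minutes are valued at the
#' role's hourly full wage; accelerator minutes at the arm's accelerator
#' hourly rate (amortization + external maintenance + annual QC/IM labor,
#' per operating hour); TPS minutes at the TPS hourly rate for VMAT
#' patients only — helical tomotherapy has no separate TPS, so its TPS
#' components are identically zero. Derived sums satisfy
#' `total_cost = planning_cost + session_cost` exactly.
#'
#' @param events resource-use tibble as produced by
#'   [generate_resource_use()] (columns `patient_id`, `phase`, `role`,
#'   `personnel_minutes`, `equipment`, `equipment_minutes`).
#' @param unit_costs a [unit_cost_table()].
#' @param patients tibble mapping `patient_id` to `arm` (extra columns
#'   ignored).
#' @return A tibble with one row per patient: `patient_id`, `arm`, the
#'   nine components of [cost_components()], and derived `planning_cost`,
#'   `session_cost`, `total_cost` (euros).
#' @export
cost_cohort <- function(events, unit_costs, patients) {
  stopifnot(inherits(unit_costs, "unit_cost_table"))
  patients <- dplyr::distinct(patients[, c("patient_id", "arm")])
  if (!all(patients$arm %in% .ARMS))
    stop("arm must be one of: ", paste(.ARMS, collapse = ", "))
  bad_phase <- setdiff(unique(events$phase), .PHASES)
  if (length(bad_phase) > 0)
    stop("unknown phase(s): ", paste(bad_phase, collapse = ", "))
  orphan <- setdiff(unique(events$patient_id), patients$patient_id)
  if (length(orphan) > 0)
    stop("events reference patients with no arm: ",
         paste(utils::head(orphan, 5), collapse = ", "))
  if (any(events$personnel_minutes < 0, na.rm = TRUE) ||
      any(events$equipment_minutes < 0, na.rm = TRUE))
    stop("minutes must be non-negative")

  wages <- role_hourly_wages(unit_costs)
  need_role <- unique(events$role[!is.na(events$role) &
                                    events$personnel_minutes > 0])
  missing_role <- setdiff(need_role, names(wages))
  if (length(missing_role) > 0)
    stop("no wage defined for role(s): ", paste(missing_role, collapse = ", "))

  ev <- dplyr::left_join(events, patients, by = "patient_id")

  accel_rate <- c(VMAT = machine_hourly_rate(unit_costs, "accelerator_VMAT"),
                  HT = machine_hourly_rate(unit_costs, "accelerator_HT"))
  tps_rate <- if ("TPS_VMAT" %in% unit_costs$equipment$machine)
    machine_hourly_rate(unit_costs, "TPS_VMAT") else NA_real_
  uses_tps <- any(ev$equipment == "TPS" & ev$equipment_minutes > 0 &
                    ev$arm == "VMAT")
  if (uses_tps && is.na(tps_rate))
    stop("no equipment specification for machine: TPS_VMAT")

  wage_rate <- ifelse(is.na(ev$role), 0, wages[ev$role])
  equip_rate <- dplyr::case_when(
    ev$equipment == "accelerator" ~ accel_rate[ev$arm],
    # HT accelerator price includes the TPS: TPS components forced to zero
    ev$equipment == "TPS" & ev$arm == "HT" ~ 0,
    ev$equipment == "TPS" ~ tps_rate,
    TRUE ~ 0)

  ev$labor_component <- .LABOR_COMPONENT[ev$phase]
  ev$equip_component <-
    .EQUIP_COMPONENT[paste(ev$phase, ev$equipment, sep = ".")]
  bad_equip <- ev$equipment != "none" & ev$equipment_minutes > 0 &
    is.na(ev$equip_component)
  if (any(bad_equip))
    stop("equipment use not defined for phase/machine: ",
         paste(unique(paste(ev$phase[bad_equip], ev$equipment[bad_equip])),
               collapse = ", "))

  ev$labor_cost <- ev$personnel_minutes / 60 * wage_rate
  ev$equip_cost <- ev$equipment_minutes / 60 * equip_rate

  long <- dplyr::bind_rows(
    tibble::tibble(patient_id = ev$patient_id,
                   component = ev$labor_component, cost = ev$labor_cost),
    tibble::tibble(patient_id = ev$patient_id,
                   component = ev$equip_component, cost = ev$equip_cost))
  long <- long[!is.na(long$component), ]
  agg <- dplyr::summarise(dplyr::group_by(long, patient_id, component),
                          cost = sum(cost), .groups = "drop")
  wide <- tidyr::pivot_wider(agg, names_from = component, values_from = cost,
                             values_fill = 0)
  for (comp in setdiff(cost_components(), names(wide))) wide[[comp]] <- 0

  out <- dplyr::left_join(patients, wide, by = "patient_id")
  out[cost_components()][is.na(out[cost_components()])] <- 0
  out$planning_cost <- rowSums(out[.PLANNING_COMPONENTS])
  out$session_cost <- rowSums(out[.SESSION_COMPONENTS])
  out$total_cost <- out$planning_cost + out$session_cost
  tibble::as_tibble(out[, c("patient_id", "arm", cost_components(),
                            "planning_cost", "session_cost", "total_cost")])
}

#' @rdname cost_cohort
#' @param arm treatment arm of the single patient (`"VMAT"` or `"HT"`).
#' @details `patient_cost_breakdown()` is the single-patient form: it
#'   costs the events of exactly one patient.
#' @export
patient_cost_breakdown <- function(events, unit_costs, arm) {
  ids <- unique(events$patient_id)
  if (length(ids) != 1)
    stop("patient_cost_breakdown() expects events of exactly one patient")
  cost_cohort(events, unit_costs,
              tibble::tibble(patient_id = ids, arm = arm))
}

#' Summarize cost breakdowns into component means and SDs
#'
#' Computes (optionally weighted) means and standard deviations for every
#' cost component and the derived planning, session and total rows.
#' Weights are normalized to sum to the number of patients, so the
#' summary is invariant to rescaling the weights and unit weights give
#' the ordinary mean and SD. Because the derived rows are per-patient
#' sums, the mean rows are additive: mean planning + mean session = mean
#' total.
#'
#' @param breakdowns tibble from [cost_cohort()].
#' @param weights optional positive per-patient weights (e.g. stabilized
#'   IPTW weights), aligned with `breakdowns`.
#' @return A tibble with columns `component`, `mean`, `sd` (euros), in
#'   reporting order with the three derived rows last.
#' @export
summarize_costs <- function(breakdowns, weights = NULL) {
  n <- nrow(breakdowns)
  if (is.null(weights)) weights <- rep(1, n)
  if (length(weights) != n)
    stop("weights length (", length(weights),
         ") does not match number of breakdowns (", n, ")")
  if (any(weights <= 0)) stop("weights must be strictly positive")
  w <- weights / sum(weights) * n
  comps <- c(cost_components(), "planning_cost", "session_cost", "total_cost")
  stats_for <- function(x) {
    m <- sum(w * x) / n
    s <- if (n > 1) sqrt(sum(w * (x - m)^2) / (n - 1)) else NA_real_
    c(mean = m, sd = s)
  }
  vals <- vapply(comps, function(cp) stats_for(breakdowns[[cp]]), numeric(2))
  tibble::tibble(component = comps, mean = unname(vals["mean", ]),
                 sd = unname(vals["sd", ]))
}
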