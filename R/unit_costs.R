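#' Component structure of a per-patient cost breakdown
#'
#' The micro-costing engine decomposes the cost of one course of treatment
#' into nine components: labor and (where applicable) equipment occupancy
#' for each of the four planning phases, plus labor and accelerator
#' occupancy for treatment delivery. Helical tomotherapy has no separate
#' treatment planning system (TPS) line because its accelerator price
#' includes the TPS.
#'
#' @return Character vector of the nine component names, in reporting order.
#' @export
cost_components <- function() {
  c("image_registration_labor", "image_registration_tps",
    "inverse_planning_labor", "inverse_planning_tps",
    "patient_qc_labor",
    "setup_d0_labor", "setup_d0_accelerator",
    "session_labor", "session_accelerator")
}

#' Construct and validate a unit-cost parameter table
#'
#' A `unit_cost_table` holds every monetary parameter of the costing model:
#'
#' * `role_wages`: per staff role, the average annual full gross wage
#'   (payroll taxes included, euros/year) and the number of workable hours
#'   per year. Labor is valued at `annual_wage / workable_hours`.
#' * `equipment`: per machine (`accelerator_VMAT`, `accelerator_HT`,
#'   `TPS_VMAT`), the catalog purchase price (euros, taxes included), the
#'   straight-line amortization lifespan in years (12 for accelerators,
#'   5 for a TPS), the annual external maintenance contract (euros/year)
#'   and the annual operating hours.
#' * `qc_im_hours`: annual machine quality-control and internal-maintenance
#'   labor, as dedicated hours per machine for the medical physicist and
#'   the biomedical technician. Their annual cost is folded into the
#'   owning accelerator's hourly rate.
#'
#' @param role_wages tibble with columns `role`, `annual_wage`,
#'   `workable_hours`.
#' @param equipment tibble with columns `machine`, `price`,
#'   `lifespan_years`, `annual_maintenance`, `annual_operating_hours`.
#' @param qc_im_hours tibble with columns `machine`, `role`, `hours`.
#' @param currency_year label carried through to outputs (no inflation
#'   adjustment is applied).
#' @return An object of class `unit_cost_table`.
#' @seealso [default_unit_costs()], [read_unit_costs()]
#' @export
unit_cost_table <- function(role_wages, equipment, qc_im_hours,
                            currency_year = "EUR2019") {
  role_wages <- tibble::as_tibble(role_wages)
  equipment <- tibble::as_tibble(equipment)
  qc_im_hours <- tibble::as_tibble(qc_im_hours)
  stopifnot(
    all(c("role", "annual_wage", "workable_hours") %in% names(role_wages)),
    all(c("machine", "price", "lifespan_years", "annual_maintenance",
          "annual_operating_hours") %in% names(equipment)),
    all(c("machine", "role", "hours") %in% names(qc_im_hours))
  )
  if (any(role_wages$annual_wage < 0))
    stop("annual wages must be non-negative")
  if (any(role_wages$workable_hours <= 0))
    stop("workable yearly hours must be strictly positive")
  if (any(equipment$price < 0) || any(equipment$annual_maintenance < 0))
    stop("equipment prices and maintenance must be non-negative")
  if (any(equipment$lifespan_years <= 0) ||
      any(equipment$annual_operating_hours <= 0))
    stop("equipment lifespans and annual operating hours must be strictly positive")
  bad_roles <- setdiff(qc_im_hours$role,
                       c("medical_physicist", "biomedical_technician"))
  if (length(bad_roles) > 0)
    stop("QC/IM hours are defined only for the medical physicist and the ",
         "biomedical technician; found: ", paste(bad_roles, collapse = ", "))
  if (any(qc_im_hours$hours < 0)) stop("QC/IM hours must be non-negative")
  structure(
    list(role_wages = role_wages, equipment = equipment,
         qc_im_hours = qc_im_hours, currency_year = currency_year),
    class = "unit_cost_table")
}

#' @export
print.unit_cost_table <- function(x, ...) {
  cat("<unit_cost_table> (", x$currency_year, ")\n", sep = "")
  cat("Role wages:\n"); print(x$role_wages)
  cat("Equipment:\n"); print(x$equipment)
  cat("Annual QC/IM dedicated hours:\n"); print(x$qc_im_hours)
  invisible(x)
}

#' Default unit costs (calibrated placeholders, 2019 euros)
#'
#' Catalog prices, maintenance contracts and wage schedules of the source
#' study are not public, so these defaults are placeholders chosen at
#' plausible French 2019 values and calibrated so that the default
#' synthetic cohort reproduces the published per-arm cost-component means
#' (see [reference_cost_summary()]). In particular the accelerators'
#' annual external maintenance is back-solved from the published
#' session-accelerator means at the published session-time medians,
#' annual operating hours (2,513 h VMAT; 2,520 h HT) and annual QC/IM
#' hours (194.5 h VMAT; 144 h HT). Replace every entry with your center's
#' own values for a real costing exercise.
#'
#' @return A [unit_cost_table()].
#' @export
default_unit_costs <- function() {
  unit_cost_table(
    role_wages = tibble::tibble(
      role = .ROLES,
      annual_wage = c(55000, 60000, 90000, 150000, 45000, 50000),
      workable_hours = 1600),
    equipment = tibble::tibble(
      machine = c("accelerator_VMAT", "accelerator_HT", "TPS_VMAT"),
      price = c(2700000, 3600000, 420000),
      lifespan_years = c(12, 12, 5),
      # accelerator maintenance back-solved to the published session means
      annual_maintenance = c(242065.38, 274589.96, 16000),
      annual_operating_hours = c(2513, 2520, 2513)),
    qc_im_hours = tibble::tibble(
      machine = rep(c("accelerator_VMAT", "accelerator_HT"), each = 2L),
      role = rep(c("medical_physicist", "biomedical_technician"), 2L),
      hours = c(140, 54.5, 104, 40)),
    currency_year = "EUR2019")
}

#' Hourly valuation of labor
#'
#' Labor is valued at the average annual full gross wage (payroll taxes
#' included) divided by the number of workable yearly hours.
#'
#' @param annual_full_gross_wage euros per year.
#' @param workable_hours hours per year; must be strictly positive.
#' @return euros per hour.
#' @examples
#' hourly_wage(80000, 1600) # 50 euros/h
#' @export
hourly_wage <- function(annual_full_gross_wage, workable_hours) {
  if (any(workable_hours <= 0))
    stop("workable_hours must be strictly positive")
  if (any(annual_full_gross_wage < 0))
    stop("annual_full_gross_wage must be non-negative")
  annual_full_gross_wage / workable_hours
}

#' Hourly cost of a machine
#'
#' Equipment is valued by straight-line, undiscounted replacement cost plus
#' annual running costs: the purchase price spread over the lifespan, plus
#' the annual external maintenance contract, plus (for accelerators) the
#' annual machine QC and internal-maintenance labor cost, all divided by
#' the annual operating hours.
#'
#' @param price purchase price, euros (taxes included).
#' @param lifespan_years amortization lifespan, years (> 0).
#' @param annual_maintenance external maintenance contract, euros/year.
#' @param annual_operating_hours hours of operation per year (> 0).
#' @param qc_im_annual annual QC/internal-maintenance labor cost folded
#'   into this machine, euros/year (default 0).
#' @return euros per hour of machine occupancy.
#' @examples
#' equipment_hourly_cost(3.6e6, 12, 0, 2500) # 120 euros/h
#' @export
equipment_hourly_cost <- function(price, lifespan_years, annual_maintenance,
                                  annual_operating_hours, qc_im_annual = 0) {
  if (any(lifespan_years <= 0) || any(annual_operating_hours <= 0))
    stop("lifespan_years and annual_operating_hours must be strictly positive")
  (price / lifespan_years + annual_maintenance + qc_im_annual) /
    annual_operating_hours
}

#' Annual machine QC and internal-maintenance labor cost
#'
#' Sums, over the medical physicist and the biomedical technician, the
#' hourly full wage times the annual number of dedicated QC/IM hours for
#' the given machine.
#'
#' @param unit_costs a [unit_cost_table()].
#' @param machine machine name, e.g. `"accelerator_VMAT"`.
#' @return euros per year.
#' @export
qc_im_annual_cost <- function(unit_costs, machine) {
  stopifnot(inherits(unit_costs, "unit_cost_table"))
  rows <- unit_costs$qc_im_hours[unit_costs$qc_im_hours$machine == machine, ]
  if (nrow(rows) == 0) return(0)
  wages <- role_hourly_wages(unit_costs)
  missing <- setdiff(rows$role, names(wages))
  if (length(missing) > 0)
    stop("no wage defined for QC/IM role(s): ", paste(missing, collapse = ", "))
  sum(wages[rows$role] * rows$hours)
}

#' Hourly wages for every role in a unit-cost table
#'
#' @param unit_costs a [unit_cost_table()].
#' @return Named numeric vector, euros per hour per role.
#' @export
role_hourly_wages <- function(unit_costs) {
  stopifnot(inherits(unit_costs, "unit_cost_table"))
  with(unit_costs$role_wages,
       stats::setNames(hourly_wage(annual_wage, workable_hours), role))
}

#' Hourly rate of a machine in a unit-cost table
#'
#' Convenience wrapper around [equipment_hourly_cost()] that looks the
#' machine up in the table and folds in its annual QC/IM labor cost.
#'
#' @param unit_costs a [unit_cost_table()].
#' @param machine machine name.
#' @return euros per hour.
#' @export
machine_hourly_rate <- function(unit_costs, machine) {
  stopifnot(inherits(unit_costs, "unit_cost_table"))
  spec <- unit_costs$equipment[unit_costs$equipment$machine == machine, ]
  if (nrow(spec) != 1)
    stop("no equipment specification for machine: ", machine)
  equipment_hourly_cost(spec$price, spec$lifespan_years,
                        spec$annual_maintenance,
                        spec$annual_operating_hours,
                        qc_im_annual_cost(unit_costs, machine))
}

#' Read or write a unit-cost table as YAML
#'
#' @param path file path.
#' @param unit_costs a [unit_cost_table()].
#' @return `read_unit_costs()` returns a [unit_cost_table()];
#'   `write_unit_costs()` returns `path` invisibly.
#' @export
read_unit_costs <- function(path) {
  x <- yaml::read_yaml(path)
  unit_cost_table(
    role_wages = dplyr::bind_rows(x$role_wages),
    equipment = dplyr::bind_rows(x$equipment),
    qc_im_hours = dplyr::bind_rows(x$qc_im_hours),
    currency_year = x$currency_year %||% "EUR2019")
}

#' @rdname read_unit_costs
#' @export
write_unit_costs <- function(unit_costs, path) {
  stopifnot(inherits(unit_costs, "unit_cost_table"))
  as_rows <- function(df) lapply(seq_len(nrow(df)), function(i) as.list(df[i, ]))
  yaml::write_yaml(
    list(currency_year = unit_costs$currency_year,
         role_wages = as_rows(unit_costs$role_wages),
         equipment = as_rows(unit_costs$equipment),
         qc_im_hours = as_rows(unit_costs$qc_im_hours)),
    path, precision = 15)
  invisible(path)
}
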