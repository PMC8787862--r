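#' Bootstrap configuration
#'
#' @param iterations number of bootstrap resamples (default 1,000). A 95%
#'   interval needs at least 40 iterations so that one order statistic
#'   can be dropped per tail.
#' @param ci_level confidence level in (0, 1).
#' @param seed optional integer seed for the resampling stream.
#' @return A list of class `bootstrap_config`.
#' @export
bootstrap_config <- function(iterations = 1000L, ci_level = 0.95,
                             seed = NULL) {
  if (ci_level <= 0 || ci_level >= 1) stop("ci_level must lie in (0, 1)")
  if (iterations < 2 / (1 - ci_level))
    stop("iterations (", iterations, ") too few for a ",
         round(100 * ci_level), "% percentile interval; need at least ",
         ceiling(2 / (1 - ci_level)))
  structure(list(iterations = as.integer(iterations), ci_level = ci_level,
                 seed = seed),
            class = "bootstrap_config")
}

# rank-based percentile interval: drop ceiling(alpha/2 * B) order
# statistics at each end, no interpolation
percentile_ci <- function(stats, ci_level) {
  b <- length(stats)
  # round before ceiling so 0.025 * 1000 does not float up to 26
  k <- ceiling(round((1 - ci_level) / 2 * b, 9))
  s <- sort(stats)
  c(low = s[k + 1L], high = s[b - k])
}

#' Percentile-bootstrap confidence interval for mean total cost
#'
#' Non-parametric bootstrap of the (optionally weighted) mean total cost:
#' patients are resampled with replacement within each arm, the weighted
#' mean is recomputed per iteration (stabilized weights are re-used, not
#' re-estimated), and the interval is formed from the order statistics of
#' the iterates, dropping `ceiling(2.5%)` of values at each end for a 95%
#' interval. The point estimate is the weighted mean of the original
#' data and does not depend on the number of iterations.
#'
#' @param total_costs per-patient total cost, euros.
#' @param arm arm labels aligned with `total_costs`; resampling is
#'   stratified by arm and one row per arm is returned.
#' @param weights optional positive per-patient weights.
#' @param config a [bootstrap_config()].
#' @return A tibble with one row per arm: `arm`, `n`, `mean`, `ci_low`,
#'   `ci_high` (euros).
#' @export
bootstrap_mean_cost <- function(total_costs, arm, weights = NULL,
                                config = bootstrap_config()) {
  stopifnot(inherits(config, "bootstrap_config"))
  if (is.null(weights)) weights <- rep(1, length(total_costs))
  if (!is.null(config$seed)) set.seed(config$seed)
  b <- config$iterations
  rows <- lapply(unique(arm), function(a) {
    x <- total_costs[arm == a]
    w <- weights[arm == a]
    n <- length(x)
    if (n < 2) stop("arm ", a, " has fewer than 2 patients")
    idx <- matrix(sample.int(n, n * b, replace = TRUE), nrow = n)
    num <- colSums(matrix(w[idx] * x[idx], nrow = n))
    den <- colSums(matrix(w[idx], nrow = n))
    ci <- percentile_ci(num / den, config$ci_level)
    tibble::tibble(arm = a, n = n, mean = sum(w * x) / sum(w),
                   ci_low = ci["low"], ci_high = ci["high"])
  })
  dplyr::bind_rows(rows)
}

#' Parameters varied in the one-way sensitivity analysis
#'
#' The default tornado parameter set: the arm's accelerator purchase
#' price, its annual external maintenance, the annual operating time, the
#' accelerator immobilization time (machine occupancy during setup
#' verification and treatment sessions, perturbed jointly), the TPS
#' purchase price, and per-role wages and labor times.
#'
#' @param roles staff roles to include for wage/labor-time parameters.
#' @return Character vector of parameter names accepted by
#'   [one_way_sensitivity()].
#' @export
tornado_parameters <- function(roles = .ROLES) {
  c("annual_operating_time", "accelerator_immobilization_time",
    "accelerator_price", "external_maintenance", "tps_price",
    paste0("wage_", roles), paste0("labor_time_", roles))
}

perturb_inputs <- function(events, unit_costs, arm, parameter, factor) {
  eq <- unit_costs$equipment
  accel <- paste0("accelerator_", arm)
  machines <- c(accel, if (arm == "VMAT") "TPS_VMAT")
  if (parameter == "accelerator_price") {
    eq$price[eq$machine == accel] <- eq$price[eq$machine == accel] * factor
  } else if (parameter == "tps_price") {
    eq$price[eq$machine == "TPS_VMAT"] <-
      eq$price[eq$machine == "TPS_VMAT"] * factor
  } else if (parameter == "external_maintenance") {
    sel <- eq$machine %in% machines
    eq$annual_maintenance[sel] <- eq$annual_maintenance[sel] * factor
  } else if (parameter == "annual_operating_time") {
    sel <- eq$machine %in% machines
    eq$annual_operating_hours[sel] <- eq$annual_operating_hours[sel] * factor
  } else if (parameter == "accelerator_immobilization_time") {
    sel <- events$equipment == "accelerator"
    events$equipment_minutes[sel] <- events$equipment_minutes[sel] * factor
  } else if (grepl("^wage_", parameter)) {
    role <- sub("^wage_", "", parameter)
    if (!role %in% unit_costs$role_wages$role)
      stop("unknown sensitivity parameter: ", parameter)
    rw <- unit_costs$role_wages
    rw$annual_wage[rw$role == role] <- rw$annual_wage[rw$role == role] * factor
    unit_costs$role_wages <- rw
  } else if (grepl("^labor_time_", parameter)) {
    role <- sub("^labor_time_", "", parameter)
    if (!role %in% unit_costs$role_wages$role)
      stop("unknown sensitivity parameter: ", parameter)
    sel <- !is.na(events$role) & events$role == role
    events$personnel_minutes[sel] <- events$personnel_minutes[sel] * factor
  } else {
    stop("unknown sensitivity parameter: ", parameter)
  }
  unit_costs$equipment <- eq
  list(events = events, unit_costs = unit_costs)
}

#' One-way deterministic sensitivity analysis (tornado rows)
#'
#' Recomputes the group mean total cost with exactly one parameter
#' perturbed to `1 - delta` and `1 + delta` times its baseline value, all
#' other inputs held at baseline. Wages and prices enter the cost
#' linearly, so their endpoints are symmetric about the base case; annual
#' operating time enters hyperbolically (cost per hour scales with
#' 1/hours), so its endpoints are asymmetric.
#'
#' @param events resource-use tibble of one arm's patients.
#' @param unit_costs a [unit_cost_table()].
#' @param arm the arm (`"VMAT"` or `"HT"`) the events belong to.
#' @param parameters parameter names (default [tornado_parameters()]).
#' @param delta perturbation fraction (default 0.20).
#' @return A tibble sorted by decreasing `range`: `parameter`, `base`,
#'   `low` (mean total at `1 - delta`), `high` (at `1 + delta`), `range`
#'   (`|high - low|`), `pct_low`, `pct_high` (percent change from base).
#' @export
one_way_sensitivity <- function(events, unit_costs, arm,
                                parameters = tornado_parameters(),
                                delta = 0.20) {
  arm <- match.arg(arm, .ARMS)
  if (delta < 0 || delta >= 1) stop("delta must lie in [0, 1)")
  patients <- tibble::tibble(patient_id = unique(events$patient_id),
                             arm = arm)
  mean_total <- function(ev, uc)
    mean(cost_cohort(ev, uc, patients)$total_cost)
  base <- mean_total(events, unit_costs)
  rows <- lapply(parameters, function(p) {
    lo <- perturb_inputs(events, unit_costs, arm, p, 1 - delta)
    hi <- perturb_inputs(events, unit_costs, arm, p, 1 + delta)
    low <- mean_total(lo$events, lo$unit_costs)
    high <- mean_total(hi$events, hi$unit_costs)
    tibble::tibble(parameter = p, base = base, low = low, high = high,
                   range = abs(high - low),
                   pct_low = 100 * (low - base) / base,
                   pct_high = 100 * (high - base) / base)
  })
  dplyr::arrange(dplyr::bind_rows(rows), dplyr::desc(range))
}

#' Plot-ready tornado table
#'
#' Orders the sensitivity rows by decreasing bar length and expresses
#' each bar by its endpoints around the base-case vertical line.
#'
#' @param rows output of [one_way_sensitivity()].
#' @return A tibble `parameter`, `base`, `lower`, `upper`, `range`,
#'   sorted by decreasing `range`.
#' @export
tornado_export <- function(rows) {
  if (nrow(rows) == 0) stop("no sensitivity rows to export")
  out <- tibble::tibble(
    parameter = rows$parameter, base = rows$base,
    lower = pmin(rows$low, rows$high),
    upper = pmax(rows$low, rows$high),
    range = rows$range)
  dplyr::arrange(out, dplyr::desc(range))
}
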