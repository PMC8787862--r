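stage_log <- function(verbose, stage, ...) {
  if (verbose) message(sprintf("[%s] %s", stage, paste0(...)))
}

#' Run the full analysis pipeline on a synthetic or user-supplied cohort
#'
#' Executes the stages simulate -> cost -> weight -> analyze -> bootstrap
#' -> tornado and writes every table as plain CSV plus a JSON run
#' manifest with seeds, record counts and file digests. With a fixed
#' configuration and seed the analytic outputs are identical across
#' re-runs.
#'
#' @param out_dir output directory (created if needed).
#' @param config a [cohort_config()] (default: the study-calibrated
#'   [default_cohort_config()]).
#' @param unit_costs a [unit_cost_table()].
#' @param cohort optional pre-built `rt_cohort` (e.g. read from CSVs with
#'   [read_cohort()]); if supplied the simulate stage is skipped.
#' @param seed optional integer overriding `config$seed`; also seeds the
#'   bootstrap stream (as `seed + 1`).
#' @param bootstrap_iterations resamples for the cost CIs.
#' @param delta tornado perturbation fraction.
#' @param verbose emit per-stage log messages.
#' @return Invisibly, a list with every stage result and the manifest.
#' @export
run_pipeline <- function(out_dir, config = default_cohort_config(),
                         unit_costs = default_unit_costs(), cohort = NULL,
                         seed = NULL, bootstrap_iterations = 1000L,
                         delta = 0.20, verbose = TRUE) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  t0 <- Sys.time()
  if (!is.null(seed)) config$seed <- as.integer(seed)

  run_stage <- function(stage, expr) {
    tryCatch(expr, error = function(e)
      stop("stage '", stage, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  if (is.null(cohort)) {
    cohort <- run_stage("simulate", generate_cohort(config))
    stage_log(verbose, "simulate", nrow(cohort$patients), " patients, ",
              nrow(cohort$resource_use), " events (seed ", config$seed, ")")
  } else {
    stage_log(verbose, "simulate", "skipped: user-supplied cohort with ",
              nrow(cohort$patients), " patients")
  }
  write_cohort(cohort, out_dir)
  patients <- cohort$patients

  costs <- run_stage("cost",
                     cost_cohort(cohort$resource_use, unit_costs, patients))
  readr::write_csv(costs, file.path(out_dir, "costs.csv"))
  stage_log(verbose, "cost", nrow(costs), " breakdowns")

  weights <- run_stage("weight", weight_cohort(patients))
  balance <- run_stage("weight",
                       balance_table(patients, weights$stabilized_weight))
  readr::write_csv(weights, file.path(out_dir, "weights.csv"))
  readr::write_csv(balance, file.path(out_dir, "balance.csv"))
  stage_log(verbose, "weight", "stabilized weights sum to ",
            round(sum(weights$stabilized_weight), 2), " (n = ",
            nrow(patients), ")")

  sw <- weights$stabilized_weight
  cost_summary <- run_stage("analyze", dplyr::bind_rows(
    dplyr::mutate(dplyr::bind_rows(lapply(.ARMS, function(a) {
      sel <- costs$arm == a
      dplyr::mutate(summarize_costs(costs[sel, ], sw[sel]), arm = a)
    })), weighting = "IPTW"),
    dplyr::mutate(dplyr::bind_rows(lapply(.ARMS, function(a) {
      sel <- costs$arm == a
      dplyr::mutate(summarize_costs(costs[sel, ]), arm = a)
    })), weighting = "unweighted")))
  readr::write_csv(cost_summary, file.path(out_dir, "cost_summary.csv"))

  effects <- run_stage("analyze", {
    rows <- list(
      weighted_linear_model(costs$total_cost, patients$arm, patients$plan),
      weighted_linear_model(costs$total_cost, patients$arm, patients$plan,
                            weights = sw))
    obs <- patients$toxicity_observed
    for (w in c("acute", "late")) {
      for (ep in .ENDPOINTS) {
        cg <- collapse_grades(cohort$toxicity, ep, w,
                              patient_ids = patients$patient_id[obs])
        ord <- match(cg$patient_id, patients$patient_id)
        lbl <- paste(w, ep, "toxicity")
        for (use_w in c(FALSE, TRUE)) {
          ww <- if (use_w) sw[ord] else NULL
          row <- tryCatch(
            weighted_ordinal_model(cg$grade, patients$arm[ord],
                                   patients$plan[ord], ww, outcome = lbl),
            error = function(e) {
              stage_log(verbose, "analyze", lbl, " skipped: ",
                        conditionMessage(e))
              NULL
            })
          rows[[length(rows) + 1L]] <- row
        }
      }
    }
    dplyr::bind_rows(rows)
  })
  readr::write_csv(effects, file.path(out_dir, "effects.csv"))

  tox_table <- run_stage("analyze",
                         toxicity_table(patients, cohort$toxicity, weights))
  readr::write_csv(tox_table, file.path(out_dir, "toxicity_table.csv"))
  stage_log(verbose, "analyze", nrow(effects), " effect rows")

  boot_cfg <- bootstrap_config(iterations = bootstrap_iterations,
                               seed = config$seed + 1L)
  boot <- run_stage("bootstrap",
                    bootstrap_mean_cost(costs$total_cost, costs$arm, sw,
                                        boot_cfg))
  readr::write_csv(boot, file.path(out_dir, "bootstrap.csv"))
  stage_log(verbose, "bootstrap", bootstrap_iterations, " iterations")

  tornado <- run_stage("tornado", dplyr::bind_rows(lapply(.ARMS, function(a) {
    ids <- patients$patient_id[patients$arm == a]
    ev <- cohort$resource_use[cohort$resource_use$patient_id %in% ids, ]
    dplyr::mutate(one_way_sensitivity(ev, unit_costs, a, delta = delta),
                  arm = a, .before = 1)
  })))
  readr::write_csv(tornado, file.path(out_dir, "tornado.csv"))
  stage_log(verbose, "tornado", "delta = ", delta)

  outputs <- c("cohort.csv", "resource_use.csv", "toxicity_events.csv",
               "cohort_config.yaml", "costs.csv", "weights.csv",
               "balance.csv", "cost_summary.csv", "effects.csv",
               "toxicity_table.csv", "bootstrap.csv", "tornado.csv")
  manifest <- list(
    package_version = as.character(utils::packageVersion("rtmicrocost")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    seed = config$seed,
    bootstrap_seed = config$seed + 1L,
    n_patients = nrow(patients),
    n_vmat = sum(patients$arm == "VMAT"),
    n_ht = sum(patients$arm == "HT"),
    n_resource_events = nrow(cohort$resource_use),
    bootstrap_iterations = bootstrap_iterations,
    tornado_delta = delta,
    elapsed_seconds = as.numeric(difftime(Sys.time(), t0, units = "secs")),
    files = as.list(tools::md5sum(file.path(out_dir, outputs))))
  names(manifest$files) <- outputs
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)

  invisible(list(cohort = cohort, costs = costs, weights = weights,
                 balance = balance, cost_summary = cost_summary,
                 effects = effects, toxicity_table = tox_table,
                 bootstrap = boot, tornado = tornado, manifest = manifest))
}

#' Render pipeline outputs as a human-readable report
#'
#' Reads the CSV tables written by [run_pipeline()] and formats them:
#' balance diagnostics, cost components in reporting order with
#' unweighted and weighted columns side by side, grade distributions per
#' endpoint, effect estimates, bootstrap intervals and tornado ranking.
#' Every number shown is read from a stage output; nothing is
#' recomputed. Missing weighted columns are marked absent, not zero.
#'
#' @param out_dir directory written by [run_pipeline()].
#' @return The report as a character vector of lines, invisibly; the
#'   report is also printed.
#' @export
render_tables <- function(out_dir) {
  need <- function(f) {
    p <- file.path(out_dir, f)
    if (!file.exists(p)) stop("missing stage output: ", f)
    readr::read_csv(p, show_col_types = FALSE)
  }
  fmt <- function(x, d = 2) ifelse(is.na(x), "--", sprintf(paste0("%.", d, "f"), x))
  out <- character()
  push <- function(...) out <<- c(out, paste0(...))

  bal <- need("balance.csv")
  push("== Covariate balance (standardized differences, HT - VMAT) ==")
  push(sprintf("%-20s %-11s %12s %12s", "covariate", "kind",
               "unweighted d", "weighted d"))
  for (i in seq_len(nrow(bal)))
    push(sprintf("%-20s %-11s %12s %12s", bal$covariate[i], bal$kind[i],
                 fmt(bal$unweighted_d[i], 3), fmt(bal$weighted_d[i], 3)))

  cs <- need("cost_summary.csv")
  push("", "== Cost per patient (euros), mean (SD) ==")
  push(sprintf("%-26s %22s %22s", "component [IPTW]", "VMAT", "HT"))
  csw <- cs[cs$weighting == "IPTW", ]
  for (comp in unique(csw$component)) {
    v <- csw[csw$component == comp & csw$arm == "VMAT", ]
    h <- csw[csw$component == comp & csw$arm == "HT", ]
    cell <- function(r) if (nrow(r) == 0) "--" else
      paste0(fmt(r$mean), " (", fmt(r$sd), ")")
    push(sprintf("%-26s %22s %22s", comp, cell(v), cell(h)))
  }

  tox <- need("toxicity_table.csv")
  push("", "== Toxicity grade distributions (% of patients) ==")
  push(sprintf("%-6s %-8s %-6s %10s %10s %12s %12s", "window", "endpoint",
               "grade", "VMAT", "HT", "VMAT(IPTW)", "HT(IPTW)"))
  for (i in seq_len(nrow(tox)))
    push(sprintf("%-6s %-8s %-6s %10s %10s %12s %12s",
                 tox$window[i], tox$endpoint[i], tox$grade[i],
                 fmt(tox$pct_vmat[i], 1), fmt(tox$pct_ht[i], 1),
                 fmt(tox$wpct_vmat[i], 1), fmt(tox$wpct_ht[i], 1)))

  eff <- need("effects.csv")
  push("", "== Treatment-effect estimates ==")
  push(sprintf("%-24s %-8s %-10s %10s %8s %8s", "outcome", "model",
               "weighting", "estimate", "SE", "p"))
  for (i in seq_len(nrow(eff)))
    push(sprintf("%-24s %-8s %-10s %10s %8s %8s", eff$outcome[i],
                 eff$model[i], eff$weighting[i], fmt(eff$estimate[i]),
                 fmt(eff$se[i]), fmt(eff$p_value[i], 4)))

  boot <- need("bootstrap.csv")
  push("", "== Mean total cost, percentile bootstrap ==")
  for (i in seq_len(nrow(boot)))
    push(sprintf("%-5s mean %9s  95%% CI [%s; %s]", boot$arm[i],
                 fmt(boot$mean[i]), fmt(boot$ci_low[i]),
                 fmt(boot$ci_high[i])))

  torn <- need("tornado.csv")
  push("", "== One-way sensitivity (descending range, euros) ==")
  push(sprintf("%-5s %-34s %10s %10s %10s", "arm", "parameter", "low",
               "high", "range"))
  for (i in seq_len(nrow(torn)))
    push(sprintf("%-5s %-34s %10s %10s %10s", torn$arm[i],
                 torn$parameter[i], fmt(torn$low[i]), fmt(torn$high[i]),
                 fmt(torn$range[i])))

  cat(out, sep = "\n")
  invisible(out)
}
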