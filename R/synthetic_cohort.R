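# gamma draws parameterized by mean and sd; sd = 0 degenerates to the mean
rgamma_ms <- function(n, mean, sd) {
  out <- numeric(n)
  pos <- mean > 0 & sd > 0
  if (any(pos)) {
    shape <- (mean[pos] / sd[pos])^2
    out[pos] <- stats::rgamma(sum(pos), shape = shape,
                              rate = shape / mean[pos])
  }
  det <- mean > 0 & sd == 0
  out[det] <- mean[det]
  out
}

#' Generate baseline patients under the confounded assignment model
#'
#' Draws baseline covariates from the configured population distributions,
#' computes each patient's true probability of receiving helical
#' tomotherapy from the logistic assignment model, and assigns arms. In
#' the default mode the observed arm sizes are hit exactly: the HT arm is
#' filled by weighted sampling without replacement with the assignment
#' probabilities as weights, mirroring a study with fixed observed sizes.
#' With `exact_sizes = FALSE` assignment is unconditional Bernoulli (arm
#' sizes are then random and `n_vmat + n_ht` only sets the total); this
#' mode is the exact data-generating law of the logistic model and is the
#' one to use for parameter-recovery studies.
#'
#' @param config a [cohort_config()].
#' @param exact_sizes hit `n_vmat`/`n_ht` exactly (default) or assign by
#'   Bernoulli draws.
#' @return A tibble with one row per patient: `patient_id`, `arm`, `age`,
#'   `performance_status` (`"0"`/`"1-2"`), `c_t_stage` (`"cT1"`-`"cT4"`),
#'   `c_n_stage` (`"cN0"`/`"cN1"`), `psa` (capped, ng/ml), `plan`
#'   (`"SIB"`/`"sequential"`), `n_fractions` (34 or 40),
#'   `toxicity_observed`.
#' @export
generate_patients <- function(config, exact_sizes = TRUE) {
  validate_cohort_config(config)
  cv <- config$covariates
  a <- config$assignment
  n <- config$n_vmat + config$n_ht

  age <- stats::rnorm(n, cv$age_mean, cv$age_sd)
  ps12 <- stats::rbinom(n, 1, cv$p_ps12)
  ct <- sample.int(4L, n, replace = TRUE, prob = cv$ct_probs)
  cn1 <- stats::rbinom(n, 1, cv$p_cn1)
  psa <- pmin(stats::rlnorm(n, cv$psa_meanlog, cv$psa_sdlog), cv$psa_cap)

  # age and PSA enter centered at their population location so the
  # intercept controls the marginal treatment probability
  eta <- a$intercept + a$age * (age - cv$age_mean) +
    a$performance_status * ps12 +
    a$ct2 * (ct == 2) + a$ct3 * (ct == 3) + a$ct4 * (ct == 4) +
    a$cn1 * cn1 + a$psa * (psa - exp(cv$psa_meanlog))
  p_ht <- stats::plogis(eta)

  if (exact_sizes) {
    if (sum(p_ht > 0) < config$n_ht)
      stop("assignment model cannot fill the HT arm: only ",
           sum(p_ht > 0), " patients have positive assignment probability")
    if (sum(p_ht < 1) < config$n_vmat)
      stop("assignment model cannot fill the VMAT arm: only ",
           sum(p_ht < 1), " patients have probability below one")
    ht_idx <- sample.int(n, config$n_ht, prob = p_ht)
    arm <- rep("VMAT", n)
    arm[ht_idx] <- "HT"
  } else {
    arm <- ifelse(stats::rbinom(n, 1, p_ht) == 1, "HT", "VMAT")
  }

  plan <- ifelse(stats::rbinom(n, 1, config$plan_mix) == 1,
                 "sequential", "SIB")
  followed <- stats::rbinom(n, 1, config$toxicity$p_followup[arm]) == 1

  tibble::tibble(
    patient_id = sprintf("P%05d", seq_len(n)),
    arm = arm,
    age = age,
    performance_status = ifelse(ps12 == 1, "1-2", "0"),
    c_t_stage = paste0("cT", ct),
    c_n_stage = ifelse(cn1 == 1, "cN1", "cN0"),
    psa = psa,
    plan = plan,
    n_fractions = ifelse(plan == "sequential", 40L, 34L),
    toxicity_observed = followed)
}

#' Sample treatment-session durations
#'
#' Session times follow a log-normal distribution parameterized by its
#' median, with the median depending on the arm and the session stratum
#' (first session; sessions 2-3; sessions 4 and later). The strata encode
#' the learning-curve effect: under the defaults VMAT session medians fall
#' from 20 to 15 to 13 minutes across strata while helical tomotherapy
#' stays near 18/18/17 minutes. `session_sdlog = 0` gives degenerate
#' draws exactly at the stratum median.
#'
#' @param arm `"VMAT"` or `"HT"`.
#' @param session_index session number(s), starting at 1.
#' @param timing the `timing` element of a [cohort_config()].
#' @return Minutes, same length as `session_index`.
#' @export
sample_session_duration <- function(arm, session_index, timing) {
  if (any(session_index < 1)) stop("session_index must be >= 1")
  arm <- match.arg(arm, .ARMS)
  med <- timing$session_medians[[arm]]
  stratum <- ifelse(session_index == 1, 1L, ifelse(session_index <= 3, 2L, 3L))
  if (timing$session_sdlog == 0) return(med[stratum])
  stats::rlnorm(length(session_index), meanlog = log(med[stratum]),
                sdlog = timing$session_sdlog)
}

#' Generate the per-patient resource-use log
#'
#' Produces one timed activity row per planning-phase resource (labor, and
#' machine occupancy where the phase uses the TPS or the accelerator) and
#' one row per treatment session. Every patient's log covers all four
#' planning phases and exactly `n_fractions` sessions (34 for a
#' simultaneous-integrated-boost plan, 40 for a sequential plan). Session
#' rows carry both the accelerator occupancy and the attending personnel
#' time (occupancy times the configured staffing factor).
#'
#' @param patients tibble from [generate_patients()].
#' @param config the generating [cohort_config()].
#' @return A tibble with columns `patient_id`, `phase`, `session_index`
#'   (`NA` for planning phases), `role`, `personnel_minutes`, `equipment`
#'   (`"accelerator"`, `"TPS"` or `"none"`), `equipment_minutes`.
#' @export
generate_resource_use <- function(patients, config) {
  plan_spec <- config$timing$planning

  planning <- dplyr::inner_join(
    patients[, c("patient_id", "arm")], plan_spec,
    by = "arm", relationship = "many-to-many")
  planning$personnel_minutes <- rgamma_ms(nrow(planning),
                                          planning$labor_mean,
                                          planning$labor_sd)
  planning$equipment_minutes <- rgamma_ms(nrow(planning),
                                          planning$equip_mean,
                                          planning$equip_sd)
  labor_rows <- dplyr::transmute(
    planning, patient_id, phase, session_index = NA_integer_, role,
    personnel_minutes, equipment = "none", equipment_minutes = 0)
  equip_rows <- dplyr::transmute(
    dplyr::filter(planning, equipment != "none"),
    patient_id, phase, session_index = NA_integer_, role = NA_character_,
    personnel_minutes = 0, equipment, equipment_minutes)

  sess <- patients[rep(seq_len(nrow(patients)), patients$n_fractions),
                   c("patient_id", "arm")]
  sess$session_index <- unlist(lapply(patients$n_fractions, seq_len))
  dur <- numeric(nrow(sess))
  for (arm in .ARMS) {
    sel <- sess$arm == arm
    if (any(sel))
      dur[sel] <- sample_session_duration(arm, sess$session_index[sel],
                                          config$timing)
  }
  session_rows <- tibble::tibble(
    patient_id = sess$patient_id,
    phase = "session",
    session_index = as.integer(sess$session_index),
    role = "radiation_therapist",
    personnel_minutes =
      config$timing$session_labor_factor[sess$arm] * dur,
    equipment = "accelerator",
    equipment_minutes = dur)

  out <- dplyr::bind_rows(labor_rows, equip_rows, session_rows)
  dplyr::arrange(out, patient_id, match(phase, .PHASES), session_index)
}

#' Sample collapsed ordinal toxicity grades
#'
#' Grades follow a proportional-odds (cumulative logit) model over the
#' four collapsed CTCAE categories 0 < 1 < 2 < 3-4:
#' `P(grade <= k) = plogis(cutpoint_k - effect * [arm == "VMAT"])`, so a
#' positive treatment effect gives VMAT higher odds of a worse grade.
#' Acute records get a uniform event month in (0, 3]; late records a
#' uniform month in [6, 24].
#'
#' @param patients tibble with columns `patient_id` and `arm` (typically
#'   from [generate_patients()]).
#' @param endpoint `"GI"`, `"GU"` or `"sexual"`.
#' @param window `"acute"` or `"late"`.
#' @param model the `toxicity` element of a [cohort_config()] (fields
#'   `cutpoints` and `effect`).
#' @return A tibble with columns `patient_id`, `endpoint`, `window`,
#'   `grade` (factor with the four ordered categories) and
#'   `months_after_treatment`.
#' @export
sample_toxicity <- function(patients, endpoint, window, model) {
  endpoint <- match.arg(endpoint, .ENDPOINTS)
  window <- match.arg(window, c("acute", "late"))
  cp <- check_cutpoints(model$cutpoints[[endpoint]][[window]])
  beta <- model$effect[[endpoint]][[window]]
  n <- nrow(patients)
  eta <- beta * (patients$arm == "VMAT")
  cum <- stats::plogis(outer(eta, cp, function(e, z) z - e))  # n x 3
  u <- stats::runif(n)
  idx <- 1L + rowSums(u > cum)
  months <- if (window == "acute") stats::runif(n, 0, 3)
            else stats::runif(n, 6, 24)
  tibble::tibble(
    patient_id = patients$patient_id,
    endpoint = endpoint,
    window = window,
    grade = factor(.GRADES[idx], levels = .GRADES, ordered = TRUE),
    months_after_treatment = months)
}

#' Probabilities of the four collapsed grades under the toxicity model
#'
#' Closed-form category probabilities of the proportional-odds model used
#' by [sample_toxicity()].
#'
#' @param cutpoints three strictly increasing cumulative-logit cutpoints.
#' @param effect treatment log-odds added to the linear predictor.
#' @return Numeric vector of length 4 summing to 1.
#' @examples
#' toxicity_grade_probs(c(-2.19, -0.04, 3.18))
#' @export
toxicity_grade_probs <- function(cutpoints, effect = 0) {
  check_cutpoints(cutpoints)
  diff(c(0, stats::plogis(cutpoints - effect), 1))
}

#' Generate a complete synthetic cohort
#'
#' Runs the three generation stages under a single seeded RNG stream, in
#' the documented order: patients (covariates, assignment, plan,
#' follow-up), then the resource-use log, then toxicity records for every
#' endpoint and window (records are generated only for patients with
#' toxicity follow-up). Identical configurations produce identical
#' cohorts.
#'
#' @param config a [cohort_config()]; `config$seed` seeds the stream.
#' @param exact_sizes passed to [generate_patients()].
#' @return A list of class `rt_cohort` with tibbles `patients`,
#'   `resource_use` and `toxicity`, and the generating `config`.
#' @examples
#' cohort <- generate_cohort(default_cohort_config(n_vmat = 20, n_ht = 10))
#' table(cohort$patients$arm)
#' @export
generate_cohort <- function(config, exact_sizes = TRUE) {
  validate_cohort_config(config)
  set.seed(config$seed)
  patients <- generate_patients(config, exact_sizes = exact_sizes)
  resource_use <- generate_resource_use(patients, config)
  followed <- patients[patients$toxicity_observed, , drop = FALSE]
  toxicity <- dplyr::bind_rows(lapply(c("acute", "late"), function(w) {
    dplyr::bind_rows(lapply(.ENDPOINTS, function(ep) {
      sample_toxicity(followed, ep, w, config$toxicity)
    }))
  }))
  structure(list(patients = patients, resource_use = resource_use,
                 toxicity = toxicity, config = config),
            class = "rt_cohort")
}

#' @export
print.rt_cohort <- function(x, ...) {
  cat("<rt_cohort>", nrow(x$patients), "patients (",
      sum(x$patients$arm == "VMAT"), "VMAT /",
      sum(x$patients$arm == "HT"), "HT ),",
      nrow(x$resource_use), "resource-use events,",
      nrow(x$toxicity), "toxicity records\n")
  invisible(x)
}

#' Write or read a cohort as plain CSV files plus its configuration
#'
#' Writes `cohort.csv`, `resource_use.csv`, `toxicity_events.csv` and
#' `cohort_config.yaml` into `dir`.
#'
#' @param cohort an `rt_cohort` from [generate_cohort()].
#' @param dir output directory (created if needed).
#' @return `write_cohort()` returns `dir` invisibly; `read_cohort()`
#'   returns an `rt_cohort`.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "rt_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  readr::write_csv(cohort$patients, file.path(dir, "cohort.csv"))
  readr::write_csv(cohort$resource_use, file.path(dir, "resource_use.csv"))
  readr::write_csv(cohort$toxicity, file.path(dir, "toxicity_events.csv"))
  write_cohort_config(cohort$config, file.path(dir, "cohort_config.yaml"))
  invisible(dir)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(dir) {
  tox <- readr::read_csv(file.path(dir, "toxicity_events.csv"),
                         show_col_types = FALSE)
  tox$grade <- factor(as.character(tox$grade), levels = .GRADES,
                      ordered = TRUE)
  structure(
    list(patients = readr::read_csv(file.path(dir, "cohort.csv"),
                                    show_col_types = FALSE),
         resource_use = readr::read_csv(file.path(dir, "resource_use.csv"),
                                        show_col_types = FALSE),
         toxicity = tox,
         config = read_cohort_config(file.path(dir, "cohort_config.yaml"))),
    class = "rt_cohort")
}
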