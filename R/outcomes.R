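#' Collapse toxicity records to one worst grade per patient
#'
#' The analysis grade for a window is the worst (maximum) collapsed grade
#' among a patient's records inside the window: months <= 3 for acute,
#' 6 <= months <= 24 for late. Patients with no in-window record get
#' grade 0. Collapsing is idempotent and independent of record order.
#'
#' @param toxicity tibble of toxicity records (`patient_id`, `endpoint`,
#'   `grade`, `months_after_treatment`).
#' @param endpoint `"GI"`, `"GU"` or `"sexual"`.
#' @param window `"acute"` or `"late"`.
#' @param patient_ids optional character vector of patients to report; by
#'   default the patients present in `toxicity`. Patients without
#'   in-window records are reported as grade 0.
#' @return A tibble `patient_id`, `grade` (ordered factor 0 < 1 < 2 < 3-4).
#' @export
collapse_grades <- function(toxicity, endpoint, window = c("acute", "late"),
                            patient_ids = NULL) {
  window <- match.arg(window)
  endpoint <- match.arg(endpoint, .ENDPOINTS)
  if (is.null(patient_ids)) patient_ids <- unique(toxicity$patient_id)
  m <- toxicity$months_after_treatment
  in_window <- if (window == "acute") m <= 3 else m >= 6 & m <= 24
  sel <- toxicity$endpoint == endpoint & in_window &
    toxicity$patient_id %in% patient_ids
  g <- factor(as.character(toxicity$grade), levels = .GRADES, ordered = TRUE)
  worst <- tapply(as.integer(g[sel]), toxicity$patient_id[sel], max)
  idx <- rep(1L, length(patient_ids))
  names(idx) <- patient_ids
  idx[names(worst)] <- as.integer(worst)
  tibble::tibble(
    patient_id = patient_ids,
    grade = factor(.GRADES[idx], levels = .GRADES, ordered = TRUE))
}

# analytic per-observation score of the weighted cumulative-logit
# log-likelihood at the polr() fit, in polr's parameter order
# (coefficients, then cutpoints); used for the sandwich variance
polr_scores <- function(fit, x, y, weights) {
  beta <- stats::coef(fit)
  zeta <- fit$zeta
  nj <- length(zeta) + 1L
  eta <- drop(x %*% beta)
  zlo <- c(-Inf, zeta)[y]        # cutpoint below observed category
  zhi <- c(zeta, Inf)[y]         # cutpoint above
  f_lo <- ifelse(is.finite(zlo), stats::dlogis(zlo - eta), 0)
  f_hi <- ifelse(is.finite(zhi), stats::dlogis(zhi - eta), 0)
  p <- stats::plogis(zhi - eta) - stats::plogis(zlo - eta)
  s_beta <- x * ((f_lo - f_hi) / p)
  s_zeta <- matrix(0, nrow = length(y), ncol = length(zeta))
  for (k in seq_along(zeta)) {
    s_zeta[, k] <- (as.integer(y == k) * f_hi -
                      as.integer(y == k + 1L) * f_lo) / p
  }
  cbind(s_beta, s_zeta) * weights
}

effect_row <- function(outcome, model, term, estimate, se, weighting) {
  z <- estimate / se
  tibble::tibble(outcome = outcome, model = model, term = term,
                 estimate = estimate, se = se, statistic = z,
                 p_value = 2 * stats::pnorm(-abs(z)), weighting = weighting)
}

#' Weighted proportional-odds model for collapsed toxicity grades
#'
#' Cumulative-logit (proportional-odds) regression of the ordered grade
#' on the treatment arm, optionally adjusting for plan type, by weighted
#' maximum likelihood ([MASS::polr()]). The arm term is an indicator for
#' VMAT, so a positive coefficient means higher odds of a worse grade
#' under VMAT. Standard errors are robust (sandwich) with the weights
#' treated as fixed, assembled from analytic per-observation scores;
#' p-values are Wald.
#'
#' @param grades ordered factor (or vector coercible to the 0 < 1 < 2 <
#'   3-4 scale), one per patient.
#' @param arm arm labels aligned with `grades`.
#' @param plan optional plan labels (`"SIB"`/`"sequential"`); adds a
#'   sequential-plan indicator to the model.
#' @param weights optional positive weights (e.g. stabilized IPTW).
#' @param outcome label stored in the result.
#' @return A one-row tibble: `outcome`, `model`, `term`, `estimate`
#'   (treatment log-odds), `se`, `statistic`, `p_value`, `weighting`.
#' @export
weighted_ordinal_model <- function(grades, arm, plan = NULL, weights = NULL,
                                   outcome = "toxicity") {
  grades <- droplevels(factor(as.character(grades), levels = .GRADES,
                              ordered = TRUE))
  if (nlevels(grades) < 2)
    stop("all grades identical: ordinal model is undefined")
  n <- length(grades)
  if (is.null(weights)) weights <- rep(1, n)
  dat <- data.frame(grade = grades,
                    arm_vmat = as.integer(arm == "VMAT"))
  fml <- grade ~ arm_vmat
  if (!is.null(plan)) {
    dat$plan_seq <- as.integer(plan == "sequential")
    if (length(unique(dat$plan_seq)) > 1) fml <- grade ~ arm_vmat + plan_seq
  }
  if (nlevels(grades) == 2) {
    # the cumulative-logit model with a single cutpoint is binary
    # logistic regression on the worse category
    dat$worse <- as.integer(dat$grade == levels(dat$grade)[2])
    bfml <- stats::update(fml, worse ~ .)
    dat$.w <- weights
    bfit <- suppressWarnings(
      stats::glm(bfml, family = stats::binomial(), data = dat,
                 weights = .w))
    if (!bfit$converged)
      stop("binary cumulative-logit fit did not converge")
    est <- stats::coef(bfit)[["arm_vmat"]]
    se <- sqrt(sandwich::vcovHC(bfit, type = "HC0")["arm_vmat", "arm_vmat"])
    weighting <- if (all(weights == 1)) "unweighted" else "IPTW"
    out <- effect_row(outcome, "ordinal", "arm_vmat", est, se, weighting)
    attr(out, "fit") <- bfit
    return(out)
  }
  fit <- tryCatch(
    withCallingHandlers(
      MASS::polr(fml, data = dat, weights = weights, Hess = TRUE),
      # polr's binomial starting fit warns on fractional IPTW weights
      warning = function(w) {
        if (grepl("non-integer #successes", conditionMessage(w)))
          invokeRestart("muffleWarning")
      }),
    error = function(e) stop("proportional-odds fit failed: ",
                             conditionMessage(e), call. = FALSE))
  if (fit$convergence != 0)
    stop("proportional-odds fit did not converge (optim code ",
         fit$convergence, ")")
  x <- stats::model.matrix(fml, dat)[, -1, drop = FALSE]
  scores <- polr_scores(fit, x, as.integer(dat$grade), weights)
  bread <- stats::vcov(fit)
  vc <- bread %*% crossprod(scores) %*% bread
  est <- stats::coef(fit)[["arm_vmat"]]
  se <- sqrt(vc[1, 1])
  weighting <- if (all(weights == 1)) "unweighted" else "IPTW"
  out <- effect_row(outcome, "ordinal", "arm_vmat", est, se, weighting)
  attr(out, "fit") <- fit
  out
}

#' Weighted linear model for total cost
#'
#' Weighted least squares of per-patient total cost on the treatment arm,
#' optionally adjusting for plan type. The arm term is an indicator for
#' HT, so the coefficient is the adjusted HT minus VMAT cost difference
#' in euros. Standard errors are robust (HC0 sandwich), appropriate when
#' the weights are estimated IPTW weights.
#'
#' @param total_costs per-patient total cost, euros.
#' @param arm,plan,weights,outcome as in [weighted_ordinal_model()].
#' @return A one-row tibble as in [weighted_ordinal_model()], with
#'   `estimate` in euros.
#' @export
weighted_linear_model <- function(total_costs, arm, plan = NULL,
                                  weights = NULL, outcome = "total_cost") {
  if (any(!is.finite(total_costs))) stop("costs must be finite")
  n <- length(total_costs)
  if (is.null(weights)) weights <- rep(1, n)
  dat <- data.frame(cost = total_costs, arm_ht = as.integer(arm == "HT"),
                    .w = weights)
  fml <- cost ~ arm_ht
  if (!is.null(plan)) {
    dat$plan_seq <- as.integer(plan == "sequential")
    if (length(unique(dat$plan_seq)) > 1) fml <- cost ~ arm_ht + plan_seq
  }
  fit <- stats::lm(fml, data = dat, weights = .w)
  if (anyNA(stats::coef(fit)))
    stop("collinear design: arm/plan terms are not jointly estimable")
  vc <- sandwich::vcovHC(fit, type = "HC0")
  est <- stats::coef(fit)[["arm_ht"]]
  se <- sqrt(vc["arm_ht", "arm_ht"])
  weighting <- if (all(weights == 1)) "unweighted" else "IPTW"
  out <- effect_row(outcome, "linear", "arm_ht", est, se, weighting)
  attr(out, "fit") <- fit
  out
}

#' Sequential versus SIB mean-cost contrast within one group
#'
#' Weighted mean total cost per plan type and their difference
#' (sequential minus SIB). A sequential plan delivers 40 fractions
#' against 34 for the simultaneous-integrated-boost plan, so at equal
#' per-session cost the sequential mean is higher.
#'
#' @param total_costs per-patient totals, euros.
#' @param plan plan labels (`"SIB"`/`"sequential"`).
#' @param weights optional positive weights.
#' @return A list with `mean_sib`, `mean_sequential` and `difference`
#'   (euros).
#' @export
plan_cost_contrast <- function(total_costs, plan, weights = NULL) {
  if (is.null(weights)) weights <- rep(1, length(total_costs))
  if (length(unique(plan)) < 2)
    stop("both plan types must be present to contrast them")
  wmean <- function(sel) sum(weights[sel] * total_costs[sel]) /
    sum(weights[sel])
  m_sib <- wmean(plan == "SIB")
  m_seq <- wmean(plan == "sequential")
  list(mean_sib = m_sib, mean_sequential = m_seq,
       difference = m_seq - m_sib)
}

#' Grade-distribution table per endpoint and window
#'
#' Collapses toxicity records per patient and tabulates the four grade
#' categories per arm, unweighted (counts and percentages) and, if
#' weights are given, weighted percentages. Only patients with toxicity
#' follow-up (`toxicity_observed`) enter.
#'
#' @param patients cohort tibble.
#' @param toxicity toxicity-record tibble.
#' @param weights optional tibble `patient_id`, `stabilized_weight` (or a
#'   numeric vector aligned with `patients`).
#' @return A tibble with one row per window x endpoint x grade:
#'   `n_vmat`, `pct_vmat`, `n_ht`, `pct_ht`, and `wpct_vmat`, `wpct_ht`
#'   when weighted.
#' @export
toxicity_table <- function(patients, toxicity, weights = NULL) {
  obs <- if ("toxicity_observed" %in% names(patients))
    patients[patients$toxicity_observed, , drop = FALSE] else patients
  wvec <- NULL
  if (!is.null(weights)) {
    if (is.data.frame(weights)) {
      wvec <- weights$stabilized_weight[match(obs$patient_id,
                                              weights$patient_id)]
    } else {
      wvec <- weights[match(obs$patient_id, patients$patient_id)]
    }
  }
  rows <- list()
  for (w in c("acute", "late")) {
    for (ep in .ENDPOINTS) {
      cg <- collapse_grades(toxicity, ep, w, patient_ids = obs$patient_id)
      arm <- obs$arm[match(cg$patient_id, obs$patient_id)]
      tab <- lapply(.ARMS, function(a) {
        sel <- arm == a
        cnt <- table(cg$grade[sel])
        pct <- 100 * cnt / sum(sel)
        wpct <- if (is.null(wvec)) rep(NA_real_, 4) else {
          ww <- wvec[sel]
          vapply(.GRADES,
                 function(g) 100 * sum(ww[cg$grade[sel] == g]) / sum(ww), 0)
        }
        list(cnt = as.integer(cnt), pct = as.numeric(pct),
             wpct = as.numeric(wpct))
      })
      names(tab) <- .ARMS
      rows[[paste(w, ep)]] <- tibble::tibble(
        window = w, endpoint = ep, grade = .GRADES,
        n_vmat = tab$VMAT$cnt, pct_vmat = tab$VMAT$pct,
        n_ht = tab$HT$cnt, pct_ht = tab$HT$pct,
        wpct_vmat = tab$VMAT$wpct, wpct_ht = tab$HT$wpct)
    }
  }
  dplyr::bind_rows(rows)
}
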