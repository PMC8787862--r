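.PS_COVARIATES <- c("age", "performance_status", "c_t_stage", "c_n_stage",
                    "psa")

#' Estimate the propensity score for helical tomotherapy
#'
#' Maximum-likelihood logistic regression of the HT indicator on the
#' baseline covariates (defaults: age, performance status, cT-stage
#' indicators against cT1, cN stage, capped PSA). Returns the fitted
#' probability of receiving HT for every patient.
#'
#' @param patients cohort tibble (one row per patient) with an `arm`
#'   column and the covariate columns.
#' @param covariates character vector of covariate column names;
#'   `character(0)` fits the intercept-only model, whose fitted value is
#'   the marginal HT proportion.
#' @return A tibble `patient_id`, `ps`, with the fitted `glm` object in
#'   attribute `"model"`.
#' @export
fit_propensity <- function(patients, covariates = .PS_COVARIATES) {
  if (!all(patients$arm %in% .ARMS))
    stop("arm must be one of: ", paste(.ARMS, collapse = ", "))
  if (min(table(factor(patients$arm, .ARMS))) < 2)
    stop("need at least 2 patients per arm")
  missing_cov <- setdiff(covariates, names(patients))
  if (length(missing_cov) > 0)
    stop("covariates absent from cohort: ",
         paste(missing_cov, collapse = ", "))
  dat <- patients[, covariates, drop = FALSE]
  for (cl in names(dat))
    if (is.character(dat[[cl]])) dat[[cl]] <- factor(dat[[cl]])
  dat$.treat_ht <- as.integer(patients$arm == "HT")
  fml <- if (length(covariates) == 0) .treat_ht ~ 1
         else stats::reformulate(covariates, response = ".treat_ht")
  fit <- stats::glm(fml, family = stats::binomial(), data = dat)
  if (!fit$converged)
    stop("propensity model did not converge after ", fit$iter,
         " IWLS iterations; review the covariates")
  ps <- as.numeric(stats::fitted(fit))
  if (any(ps < 1e-8) || any(ps > 1 - 1e-8))
    stop("propensity model yields fitted probabilities at 0 or 1 ",
         "(perfect separation); review the covariates")
  out <- tibble::tibble(patient_id = patients$patient_id, ps = ps)
  attr(out, "model") <- fit
  out
}

#' Stabilized inverse-probability-of-treatment weights
#'
#' The raw IPTW weight is `1/PS` for HT patients and `1/(1 - PS)` for
#' VMAT patients. Stabilization multiplies by the marginal probability of
#' the received treatment, so the weighted pseudo-population keeps the
#' original sample size (raw weights sum to about `2n`, stabilized
#' weights to about `n`).
#'
#' @param ps propensity scores strictly inside (0, 1).
#' @param arm arm labels (`"VMAT"`/`"HT"`), aligned with `ps`.
#' @return A tibble with columns `raw_weight` and `stabilized_weight`.
#' @export
stabilized_weights <- function(ps, arm) {
  if (length(ps) != length(arm)) stop("ps and arm lengths differ")
  if (any(ps <= 0 | ps >= 1))
    stop("propensity scores must lie strictly inside (0, 1); ",
         "no silent truncation is applied")
  is_ht <- arm == "HT"
  p_marg <- mean(is_ht)
  raw <- ifelse(is_ht, 1 / ps, 1 / (1 - ps))
  tibble::tibble(
    raw_weight = raw,
    stabilized_weight = raw * ifelse(is_ht, p_marg, 1 - p_marg))
}

#' @rdname fit_propensity
#' @details `weight_cohort()` chains the propensity fit and the weight
#'   computation, returning one row per patient with `ps`, `raw_weight`
#'   and `stabilized_weight`.
#' @export
weight_cohort <- function(patients, covariates = .PS_COVARIATES) {
  psfit <- fit_propensity(patients, covariates)
  w <- stabilized_weights(psfit$ps, patients$arm)
  out <- tibble::tibble(patient_id = patients$patient_id,
                        arm = patients$arm, ps = psfit$ps,
                        raw_weight = w$raw_weight,
                        stabilized_weight = w$stabilized_weight)
  attr(out, "model") <- attr(psfit, "model")
  out
}

weighted_moments <- function(x, w) {
  m <- sum(w * x) / sum(w)
  # frequency-weighted variance (weights read as pseudo-population counts)
  v <- sum(w * (x - m)^2) / (sum(w) - 1)
  c(mean = m, var = v)
}

#' Standardized difference between the treatment arms
#'
#' Scale-free balance diagnostic, computed HT minus VMAT:
#' * continuous: `(m_HT - m_VMAT) / sqrt((s2_HT + s2_VMAT) / 2)`;
#' * binary: `(p_HT - p_VMAT) / sqrt((p_HT(1-p_HT) + p_VMAT(1-p_VMAT))/2)`;
#' * multilevel (more than two levels): the generalized Mahalanobis form
#'   `sqrt(T' S^-1 T)` over the `L - 1` level-proportion contrasts, with
#'   `S` the average of the two within-arm multinomial covariance
#'   matrices.
#'
#' Weighted variants replace all moments by their frequency-weighted
#' counterparts; unit weights reproduce the unweighted value exactly.
#'
#' @param values covariate values.
#' @param arm arm labels aligned with `values`.
#' @param weights optional positive weights (default: unit).
#' @param kind `"auto"` (numeric -> continuous, two levels -> binary,
#'   otherwise multilevel) or one of `"continuous"`, `"binary"`,
#'   `"multilevel"`.
#' @return The standardized difference `d` (signed for continuous and
#'   binary; non-negative for multilevel).
#' @export
standardized_difference <- function(values, arm, weights = NULL,
                                    kind = c("auto", "continuous", "binary",
                                             "multilevel")) {
  kind <- match.arg(kind)
  if (is.null(weights)) weights <- rep(1, length(values))
  if (any(weights <= 0)) stop("weights must be strictly positive")
  if (length(values) != length(arm) || length(values) != length(weights))
    stop("values, arm and weights must have equal length")
  if (kind == "auto") {
    kind <- if (is.numeric(values)) "continuous"
    else if (length(unique(values)) <= 2) "binary"
    else "multilevel"
  }
  ht <- arm == "HT"; vm <- arm == "VMAT"
  if (!any(ht) || !any(vm)) stop("both arms must be present")

  if (kind == "continuous") {
    m1 <- weighted_moments(values[ht], weights[ht])
    m2 <- weighted_moments(values[vm], weights[vm])
    denom <- sqrt((m1["var"] + m2["var"]) / 2)
    if (denom == 0) stop("zero pooled variance: standardized difference undefined")
    return(unname((m1["mean"] - m2["mean"]) / denom))
  }

  f <- factor(values)
  props <- function(sel) {
    p <- vapply(levels(f), function(l) sum(weights[sel & f == l]), 0)
    p / sum(weights[sel])
  }
  p1 <- props(ht); p2 <- props(vm)

  if (kind == "binary") {
    if (nlevels(f) > 2) stop("binary kind requires at most two levels")
    # proportion of the second (last) level
    q1 <- p1[nlevels(f)]; q2 <- p2[nlevels(f)]
    denom <- sqrt((q1 * (1 - q1) + q2 * (1 - q2)) / 2)
    if (denom == 0) stop("zero pooled variance: standardized difference undefined")
    return(unname((q1 - q2) / denom))
  }

  if (nlevels(f) < 3) stop("multilevel kind requires at least three levels")
  tcon <- (p1 - p2)[-1]
  cov_of <- function(p) diag(p[-1], nrow = nlevels(f) - 1) -
    outer(p[-1], p[-1])
  s <- (cov_of(p1) + cov_of(p2)) / 2
  if (abs(det(s)) < 1e-14)
    stop("singular level-proportion covariance: standardized difference undefined")
  sqrt(drop(t(tcon) %*% solve(s) %*% tcon))
}

#' Balance table for the propensity-model covariates
#'
#' One row per baseline covariate with the unweighted and (if weights are
#' supplied) stabilized-IPTW-weighted standardized differences.
#'
#' @param patients cohort tibble.
#' @param weights optional per-patient weights (e.g. the
#'   `stabilized_weight` column of [weight_cohort()]).
#' @param covariates covariate names; the default is the propensity-model
#'   set.
#' @return A tibble `covariate`, `kind`, `unweighted_d`, `weighted_d`.
#' @export
balance_table <- function(patients, weights = NULL,
                          covariates = .PS_COVARIATES) {
  kind_of <- function(x) {
    if (is.numeric(x)) "continuous"
    else if (length(unique(x)) <= 2) "binary" else "multilevel"
  }
  rows <- lapply(covariates, function(cv) {
    x <- patients[[cv]]
    k <- kind_of(x)
    tibble::tibble(
      covariate = cv, kind = k,
      unweighted_d = standardized_difference(x, patients$arm, kind = k),
      weighted_d = if (is.null(weights)) NA_real_ else
        standardized_difference(x, patients$arm, weights, kind = k))
  })
  dplyr::bind_rows(rows)
}
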