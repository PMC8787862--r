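toy_toxicity <- function() {
  tibble::tibble(
    patient_id = "P1",
    endpoint = "GI",
    grade = factor(c("1", "2", "1"), levels = c("0", "1", "2", "3-4"),
                   ordered = TRUE),
    months_after_treatment = c(1, 2, 12))
}

test_that("grade collapsing takes the worst grade inside the window", {
  tox <- toy_toxicity()
  acute <- collapse_grades(tox, "GI", "acute")
  expect_equal(as.character(acute$grade), "2")
  late <- collapse_grades(tox, "GI", "late")
  expect_equal(as.character(late$grade), "1")
  # no records in window, or no records at all -> grade 0
  gu <- collapse_grades(tox, "GU", "acute", patient_ids = c("P1", "P2"))
  expect_equal(as.character(gu$grade), c("0", "0"))
  # order-independence and idempotence
  shuffled <- collapse_grades(tox[c(3, 1, 2), ], "GI", "acute")
  expect_equal(shuffled, acute)
})

test_that("the ordinal model recovers a known treatment log-odds ratio", {
  set.seed(71)
  n <- 20000
  patients <- tibble::tibble(patient_id = sprintf("P%05d", 1:n),
                             arm = rep(c("VMAT", "HT"), n / 2))
  beta <- 0.8
  model <- list(cutpoints = list(GI = list(acute = c(-1.5, 0.2, 2.5))),
                effect = list(GI = list(acute = beta)))
  tox <- sample_toxicity(patients, "GI", "acute", model)
  est <- weighted_ordinal_model(tox$grade, patients$arm)
  expect_lt(abs(est$estimate - beta) / est$se, 3)
  expect_equal(est$weighting, "unweighted")
  expect_true(est$p_value > 0 && est$p_value <= 1)
})

test_that("estimated coefficient increases with the generating effect", {
  set.seed(72)
  n <- 20000
  patients <- tibble::tibble(patient_id = sprintf("P%05d", 1:n),
                             arm = rep(c("VMAT", "HT"), n / 2))
  ests <- vapply(c(0, 0.5, 1.0), function(b) {
    model <- list(cutpoints = list(GU = list(acute = c(-1.5, 0.2, 2.5))),
                  effect = list(GU = list(acute = b)))
    tox <- sample_toxicity(patients, "GU", "acute", model)
    weighted_ordinal_model(tox$grade, patients$arm)$estimate
  }, 0)
  expect_true(all(diff(ests) > 0))
})

test_that("two observed categories reduce the ordinal model to binary logistic", {
  set.seed(73)
  n <- 600
  arm <- sample(c("VMAT", "HT"), n, replace = TRUE)
  worse <- rbinom(n, 1, plogis(-0.4 + 0.9 * (arm == "VMAT")))
  grades <- ifelse(worse == 1, "2", "0")
  est <- weighted_ordinal_model(grades, arm)
  ref <- glm(worse ~ I(arm == "VMAT"), family = binomial())
  expect_equal(est$estimate, unname(coef(ref)[2]), tolerance = 1e-4)
  # robust SEs agree with the sandwich estimator of the binary fit
  se_ref <- sqrt(sandwich::vcovHC(ref, type = "HC0")[2, 2])
  expect_equal(est$se, se_ref, tolerance = 1e-3)
})

test_that("degenerate grades fail loudly", {
  expect_error(weighted_ordinal_model(rep("1", 10), rep(c("VMAT", "HT"), 5)),
               "identical")
})

test_that("analytic cumulative-logit scores solve the weighted score equation", {
  set.seed(74)
  n <- 500
  arm <- sample(c("VMAT", "HT"), n, replace = TRUE)
  plan <- sample(c("SIB", "sequential"), n, replace = TRUE)
  w <- runif(n, 0.5, 2)
  model <- list(cutpoints = list(GI = list(late = c(-1, 0.5, 2))),
                effect = list(GI = list(late = 0.4)))
  tox <- sample_toxicity(tibble::tibble(patient_id = as.character(1:n),
                                        arm = arm), "GI", "late", model)
  est <- weighted_ordinal_model(tox$grade, arm, plan, w)
  fit <- attr(est, "fit")
  x <- cbind(arm_vmat = as.integer(arm == "VMAT"),
             plan_seq = as.integer(plan == "sequential"))
  sc <- rtmicrocost:::polr_scores(fit, x, as.integer(tox$grade), w)
  # at the weighted MLE the summed score vanishes
  expect_lt(max(abs(colSums(sc))), 1e-3)
})

test_that("the linear model reduces to the arm-mean difference", {
  set.seed(75)
  cost <- c(rnorm(40, 2500, 100), rnorm(20, 3100, 100))
  arm <- rep(c("VMAT", "HT"), c(40, 20))
  est <- weighted_linear_model(cost, arm)
  expect_equal(est$estimate,
               mean(cost[arm == "HT"]) - mean(cost[arm == "VMAT"]))
  # constant costs give a zero effect
  # zero residual variance trips lm's perfect-fit warning; intended here
  est0 <- suppressWarnings(weighted_linear_model(rep(2500, 60), arm))
  expect_equal(est0$estimate, 0)
})

test_that("the linear model recovers an injected 500-euro difference", {
  set.seed(76)
  n <- 4000
  arm <- sample(c("VMAT", "HT"), n, replace = TRUE)
  plan <- sample(c("SIB", "sequential"), n, replace = TRUE, prob = c(3, 1))
  cost <- 2500 + 500 * (arm == "HT") + 300 * (plan == "sequential") +
    rnorm(n, 0, 400)
  w <- runif(n, 0.5, 2)
  est <- weighted_linear_model(cost, arm, plan, w)
  expect_lt(abs(est$estimate - 500) / est$se, 3)
  expect_equal(est$weighting, "IPTW")
  # unit weights reduce the weighted fit to the unweighted one
  expect_equal(weighted_linear_model(cost, arm, plan, rep(1, n))$estimate,
               weighted_linear_model(cost, arm, plan)$estimate)
})

test_that("collinear designs fail loudly", {
  cost <- rnorm(20, 2500)
  arm <- rep(c("VMAT", "HT"), 10)
  plan <- ifelse(arm == "HT", "sequential", "SIB")  # plan aliases arm
  expect_error(weighted_linear_model(cost, arm, plan), "collinear")
})

test_that("sequential plans cost more at equal per-session cost", {
  # 40 sessions vs 34 at 50 euros per session
  plan <- rep(c("SIB", "sequential"), c(30, 10))
  cost <- ifelse(plan == "sequential", 40, 34) * 50
  ctr <- plan_cost_contrast(cost, plan)
  expect_gt(ctr$mean_sequential, ctr$mean_sib)
  expect_equal(ctr$difference, 6 * 50)
  # equal session counts force a zero difference
  ctr0 <- plan_cost_contrast(rep(34 * 50, 40), plan)
  expect_equal(ctr0$difference, 0)
  expect_error(plan_cost_contrast(cost, rep("SIB", 40)), "both plan")
})

test_that("sequential/SIB cost ratio is larger for HT than VMAT", {
  # constant HT session times vs the VMAT learning curve imply a larger
  # relative sequential premium for HT
  co <- generate_cohort(small_config(n_vmat = 300L, n_ht = 300L,
                                     seed = 140L))
  bd <- cost_cohort(co$resource_use, default_unit_costs(), co$patients)
  p <- co$patients
  ratio <- vapply(c("VMAT", "HT"), function(a) {
    sel <- p$arm == a
    ctr <- plan_cost_contrast(bd$total_cost[sel], p$plan[sel])
    ctr$mean_sequential / ctr$mean_sib
  }, 0)
  expect_gt(ratio[["HT"]], ratio[["VMAT"]])
})

test_that("toxicity tables have four grade rows per endpoint and window", {
  co <- generate_cohort(small_config(n_vmat = 60L, n_ht = 30L, seed = 33L))
  wc <- weight_cohort(co$patients)
  tt <- toxicity_table(co$patients, co$toxicity, wc)
  expect_equal(nrow(tt), 2 * 3 * 4)
  sums <- tapply(tt$pct_vmat, paste(tt$window, tt$endpoint), sum)
  expect_true(all(abs(sums - 100) < 1e-9))
  wsums <- tapply(tt$wpct_ht, paste(tt$window, tt$endpoint), sum)
  expect_true(all(abs(wsums - 100) < 1e-9))
  # only followed patients are tabulated
  expect_true(all(tt$n_vmat <= sum(co$patients$arm == "VMAT" &
                                     co$patients$toxicity_observed)))
})
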