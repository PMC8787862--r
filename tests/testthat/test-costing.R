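test_that("a zero-minute log costs zero everywhere", {
  uc <- toy_unit_costs()
  ev <- tibble::tibble(
    patient_id = "P1", phase = c("session", "patient_qc"),
    session_index = c(1L, NA), role = "radiation_therapist",
    personnel_minutes = 0, equipment = c("accelerator", "none"),
    equipment_minutes = 0)
  bd <- patient_cost_breakdown(ev, uc, "VMAT")
  expect_true(all(bd[, cost_components()] == 0))
  expect_equal(bd$total_cost, 0)
})

test_that("a three-event toy log matches hand multiplication", {
  uc <- toy_unit_costs()
  # therapist 48000/1600 = 30/h; VMAT accel (3e6/12 + 150000 + qcim)/2500
  qcim <- 100 * 96000 / 1600 + 50 * 48000 / 1600   # 6000 + 1500
  accel <- (3e6 / 12 + 150000 + qcim) / 2500       # 163 /h
  ev <- tibble::tibble(
    patient_id = "P1",
    phase = c("inverse_planning", "session", "session"),
    session_index = c(NA, 1L, 2L),
    role = c("dosimetrist", "radiation_therapist", NA),
    personnel_minutes = c(120, 30, 0),
    equipment = c("none", "none", "accelerator"),
    equipment_minutes = c(0, 0, 45))
  bd <- patient_cost_breakdown(ev, uc, "VMAT")
  expect_equal(bd$inverse_planning_labor, 120 / 60 * 37.5)
  expect_equal(bd$session_labor, 30 / 60 * 30)
  expect_equal(bd$session_accelerator, 45 / 60 * accel)
  expect_equal(bd$total_cost, 75 + 15 + 0.75 * accel)
})

test_that("breakdowns equal the brute-force per-event oracle on tiny cohorts", {
  cfg <- small_config(n_vmat = 3L, n_ht = 2L, seed = 55L)
  co <- generate_cohort(cfg)
  uc <- toy_unit_costs()
  bd <- cost_cohort(co$resource_use, uc, co$patients)
  arm_of <- setNames(as.list(co$patients$arm), co$patients$patient_id)
  oracle <- oracle_breakdown(co$resource_use, uc, arm_of)
  for (i in seq_len(nrow(bd))) {
    pid <- bd$patient_id[i]
    expect_equal(unlist(bd[i, cost_components()]),
                 oracle[[pid]][cost_components()],
                 tolerance = 1e-12, ignore_attr = TRUE)
    expect_equal(bd$total_cost[i], unname(oracle[[pid]]["total"]))
  }
})

test_that("helical tomotherapy TPS components are identically zero", {
  co <- generate_cohort(small_config(seed = 9L))
  bd <- cost_cohort(co$resource_use, default_unit_costs(), co$patients)
  ht <- bd[bd$arm == "HT", ]
  expect_true(all(ht$image_registration_tps == 0))
  expect_true(all(ht$inverse_planning_tps == 0))
  expect_true(all(bd[bd$arm == "VMAT", ]$image_registration_tps > 0))
})

test_that("accounting identities hold to 1e-9 euro", {
  co <- generate_cohort(small_config(seed = 21L))
  bd <- cost_cohort(co$resource_use, default_unit_costs(), co$patients)
  planning <- rowSums(bd[, c("image_registration_labor",
                             "image_registration_tps",
                             "inverse_planning_labor",
                             "inverse_planning_tps", "patient_qc_labor",
                             "setup_d0_labor", "setup_d0_accelerator")])
  session <- rowSums(bd[, c("session_labor", "session_accelerator")])
  expect_lt(max(abs(bd$planning_cost - planning)), 1e-9)
  expect_lt(max(abs(bd$session_cost - session)), 1e-9)
  expect_lt(max(abs(bd$total_cost - planning - session)), 1e-9)
})

test_that("costs are homogeneous of degree one in unit costs", {
  co <- generate_cohort(small_config(seed = 23L))
  uc <- toy_unit_costs()
  k <- 1.37
  uc2 <- uc
  uc2$role_wages$annual_wage <- uc$role_wages$annual_wage * k
  uc2$equipment$price <- uc$equipment$price * k
  uc2$equipment$annual_maintenance <- uc$equipment$annual_maintenance * k
  bd1 <- cost_cohort(co$resource_use, uc, co$patients)
  bd2 <- cost_cohort(co$resource_use, uc2, co$patients)
  expect_equal(bd2$total_cost, k * bd1$total_cost, tolerance = 1e-12)
})

test_that("adding an event with positive minutes never decreases a component", {
  co <- generate_cohort(small_config(n_vmat = 4L, n_ht = 2L, seed = 3L))
  uc <- toy_unit_costs()
  bd1 <- cost_cohort(co$resource_use, uc, co$patients)
  extra <- tibble::tibble(
    patient_id = co$patients$patient_id[1], phase = "patient_qc",
    session_index = NA_integer_, role = "medical_physicist",
    personnel_minutes = 11, equipment = "none", equipment_minutes = 0)
  bd2 <- cost_cohort(dplyr::bind_rows(co$resource_use, extra), uc,
                     co$patients)
  m1 <- as.matrix(bd1[order(bd1$patient_id), cost_components()])
  m2 <- as.matrix(bd2[order(bd2$patient_id), cost_components()])
  expect_true(all(m2 - m1 >= -1e-12))
  expect_gt(sum(m2 - m1), 0)
})

test_that("unknown roles, phases and machines fail loudly", {
  uc <- toy_unit_costs()
  ev <- tibble::tibble(patient_id = "P1", phase = "session",
                       session_index = 1L, role = "janitor",
                       personnel_minutes = 10, equipment = "none",
                       equipment_minutes = 0)
  expect_error(patient_cost_breakdown(ev, uc, "VMAT"), "janitor")
  ev$role <- "radiation_therapist"; ev$phase <- "teleportation"
  expect_error(patient_cost_breakdown(ev, uc, "VMAT"), "teleportation")
  uc2 <- uc
  uc2$equipment <- uc$equipment[uc$equipment$machine != "accelerator_HT", ]
  ev2 <- tibble::tibble(patient_id = "P1", phase = "session",
                        session_index = 1L, role = "radiation_therapist",
                        personnel_minutes = 10, equipment = "accelerator",
                        equipment_minutes = 10)
  expect_error(patient_cost_breakdown(ev2, uc2, "HT"), "accelerator_HT")
})

test_that("summaries reduce to plain means/SDs under unit weights", {
  co <- generate_cohort(small_config(seed = 77L))
  bd <- cost_cohort(co$resource_use, default_unit_costs(), co$patients)
  s0 <- summarize_costs(bd)
  s1 <- summarize_costs(bd, rep(1, nrow(bd)))
  expect_equal(s0, s1)
  expect_equal(s0$mean[s0$component == "total_cost"], mean(bd$total_cost))
  expect_equal(s0$sd[s0$component == "total_cost"], sd(bd$total_cost))
  # additivity of the derived mean rows
  get <- function(cp) s0$mean[s0$component == cp]
  expect_equal(get("total_cost"), get("planning_cost") + get("session_cost"),
               ignore_attr = TRUE)
})

test_that("summaries are invariant to rescaling the weights", {
  co <- generate_cohort(small_config(seed = 78L))
  bd <- cost_cohort(co$resource_use, default_unit_costs(), co$patients)
  w <- runif(nrow(bd), 0.5, 2)
  expect_equal(summarize_costs(bd, w), summarize_costs(bd, 7.3 * w))
  # duplicating every patient leaves the means unchanged
  s1 <- summarize_costs(bd, w)
  s2 <- summarize_costs(dplyr::bind_rows(bd, bd), c(w, w))
  expect_equal(s2$mean, s1$mean)
  expect_error(summarize_costs(bd, w[-1]), "length")
})

test_that("published component means sum to the published aggregate rows", {
  ref <- reference_cost_summary()
  for (spec in list(list(arm = "VMAT", planning = 566.19,
                         session = 1978.18, total = 2544.37),
                    list(arm = "HT", planning = 188.64,
                         session = 2880.13, total = 3068.77))) {
    m <- setNames(ref$mean[ref$arm == spec$arm],
                  ref$component[ref$arm == spec$arm])
    planning <- sum(m[c("image_registration_labor", "image_registration_tps",
                        "inverse_planning_labor", "inverse_planning_tps",
                        "patient_qc_labor", "setup_d0_labor",
                        "setup_d0_accelerator")])
    session <- sum(m[c("session_labor", "session_accelerator")])
    # printed aggregates carry +-0.01 rounding artifacts
    expect_equal(planning, spec$planning, tolerance = 0.02 / spec$planning)
    expect_equal(session, spec$session, tolerance = 0.02 / spec$session)
    expect_equal(planning + session, spec$total,
                 tolerance = 0.03 / spec$total)
  }
})
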