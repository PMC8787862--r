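# Small fixtures shared across test files; everything is built in code.

# round-number unit costs for hand-checkable arithmetic
toy_unit_costs <- function() {
  unit_cost_table(
    role_wages = tibble::tibble(
      role = c("radiation_therapist", "dosimetrist", "medical_physicist",
               "radiation_oncologist", "resident", "biomedical_technician"),
      annual_wage = c(48000, 60000, 96000, 144000, 36000, 48000),
      workable_hours = 1600),
    equipment = tibble::tibble(
      machine = c("accelerator_VMAT", "accelerator_HT", "TPS_VMAT"),
      price = c(3000000, 3600000, 500000),
      lifespan_years = c(12, 12, 5),
      annual_maintenance = c(150000, 200000, 20000),
      annual_operating_hours = c(2500, 2500, 2500)),
    qc_im_hours = tibble::tibble(
      machine = rep(c("accelerator_VMAT", "accelerator_HT"), each = 2),
      role = rep(c("medical_physicist", "biomedical_technician"), 2),
      hours = c(100, 50, 100, 50)))
}

small_config <- function(n_vmat = 24L, n_ht = 12L, seed = 101L) {
  default_cohort_config(n_vmat = n_vmat, n_ht = n_ht, seed = seed)
}

# a null-confounding configuration: assignment depends on nothing
null_config <- function(n_vmat, n_ht, seed = 202L) {
  cfg <- default_cohort_config(n_vmat = n_vmat, n_ht = n_ht, seed = seed)
  frac <- n_ht / (n_vmat + n_ht)
  cfg$assignment <- list(intercept = qlogis(frac), age = 0,
                         performance_status = 0, ct2 = 0, ct3 = 0, ct4 = 0,
                         cn1 = 0, psa = 0)
  cfg
}

# brute-force per-event costing oracle, independent of cost_cohort():
# walks events one by one and multiplies minutes by rates computed from
# first principles
oracle_breakdown <- function(events, uc, arm_of) {
  wages <- with(uc$role_wages, setNames(annual_wage / workable_hours, role))
  eq_rate <- function(machine) {
    sp <- uc$equipment[uc$equipment$machine == machine, ]
    qc <- uc$qc_im_hours[uc$qc_im_hours$machine == machine, ]
    qc_cost <- if (nrow(qc)) sum(wages[qc$role] * qc$hours) else 0
    (sp$price / sp$lifespan_years + sp$annual_maintenance + qc_cost) /
      sp$annual_operating_hours
  }
  comp <- setNames(
    c("image_registration_labor", "inverse_planning_labor",
      "patient_qc_labor", "setup_d0_labor", "session_labor"),
    c("image_registration_contouring", "inverse_planning", "patient_qc",
      "setup_verification_d0", "session"))
  out <- list()
  for (pid in unique(events$patient_id)) {
    arm <- arm_of[[pid]]
    acc <- eq_rate(paste0("accelerator_", arm))
    vals <- setNames(numeric(9), cost_components())
    ev <- events[events$patient_id == pid, ]
    for (i in seq_len(nrow(ev))) {
      e <- ev[i, ]
      if (!is.na(e$role) && e$personnel_minutes > 0)
        vals[comp[[e$phase]]] <- vals[comp[[e$phase]]] +
          e$personnel_minutes / 60 * wages[[e$role]]
      if (e$equipment == "accelerator" && e$equipment_minutes > 0) {
        tgt <- if (e$phase == "session") "session_accelerator"
               else "setup_d0_accelerator"
        vals[tgt] <- vals[tgt] + e$equipment_minutes / 60 * acc
      }
      if (e$equipment == "TPS" && e$equipment_minutes > 0 && arm == "VMAT") {
        tgt <- if (e$phase == "inverse_planning") "inverse_planning_tps"
               else "image_registration_tps"
        vals[tgt] <- vals[tgt] + e$equipment_minutes / 60 * eq_rate("TPS_VMAT")
      }
    }
    out[[pid]] <- c(vals, total = sum(vals))
  }
  out
}
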