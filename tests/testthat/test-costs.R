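test_that("vial counts round up per administration", {
  expect_identical(vials_needed(1200, 600), 2L)
  expect_identical(vials_needed(80 * 1.72, 30), 5L)   # cisplatin, BSA 1.72
  expect_identical(vials_needed(0, 30), 0L)
  expect_error(vials_needed(-1, 30), ">= 0")
})

test_that("per-cycle drug costs follow dose, BSA and vial wastage", {
  prof <- patient_profile()
  suge <- regimen_component("sugemalimab", 1200, "flat", 1, 600, 1732.5)
  cis <- regimen_component("cisplatin", 80, "per_m2", 1, 30, 2.68)
  fu <- regimen_component("fluorouracil", 800, "per_m2", 4, 250, 20.44)
  expect_equal(cycle_drug_cost(list(suge), prof), 2 * 1732.5)
  expect_equal(cycle_drug_cost(list(cis), prof), 5 * 2.68)
  # 800 mg/m2 x 1.72 = 1376 mg/day -> 6 vials/day x 4 days
  expect_equal(cycle_drug_cost(list(fu), prof), 6 * 4 * 20.44)
  expect_equal(cycle_drug_cost(list(suge, cis, fu), prof),
               3465 + 13.40 + 490.56)
})

test_that("one-off adverse event cost is the incidence-cost dot product", {
  cfg <- load_config()
  for (arm in c("sugemalimab_chemo", "chemo")) {
    risks <- unlist(cfg$adverse_events$risks[[arm]])
    costs <- unlist(cfg$adverse_events$unit_costs[names(risks)])
    expect_equal(ae_cost_oneoff(psmcea:::.config_cost_inputs(cfg, arm)$ae),
                 sum(risks * costs))
  }
  expect_identical(ae_cost_oneoff(NULL), 0)
  expect_identical(ae_cost_oneoff(data.frame(incidence = numeric(0),
                                             cost = numeric(0))), 0)
  expect_error(ae_cost_oneoff(data.frame(incidence = 1.2, cost = 5)), "\\[0,1\\]")
})

test_that("the assistance schedule walks its tiers then stays free", {
  sched <- pap_schedule()
  expect_true(pap_paid(sched, 1))
  expect_false(pap_paid(sched, 3))
  expect_true(pap_paid(sched, 5))       # second tier starts paying
  expect_false(pap_paid(sched, 8))      # inside the 25 free cycles
  expect_true(pap_paid(sched, 32))      # tertiary paid cycle
  expect_false(pap_paid(sched, 100))    # beyond the schedule: free
  expect_identical(sum(pap_paid(sched, 1:174)), 5L)
  expect_error(pap_paid(sched, 0), ">= 1")
})

test_that("arm cost equals an independently coded cycle loop", {
  cfg <- load_config()
  econ <- psmcea:::.config_econ(cfg)
  prof <- psmcea:::.config_profile(cfg)
  models <- psmcea:::.config_models(cfg, "whole", "sugemalimab_chemo")
  tr <- occupancy_trace(models$pfs, models$os, econ)
  reg <- psmcea:::.config_regimen(cfg, "sugemalimab_chemo")
  ci <- psmcea:::.config_cost_inputs(cfg, "sugemalimab_chemo")
  got <- arm_discounted_cost(tr, reg, ci, econ, prof)
  # brute-force oracle: explicit loop over cycles and components
  total <- sum(ci$ae$incidence * ci$ae$cost)
  for (j in seq_len(econ$n_cycles)) {
    drug <- 0
    for (comp in reg) {
      if (j <= comp$max_cycles) {
        dose <- if (comp$basis == "per_m2") comp$dose * prof$bsa_m2 else comp$dose
        drug <- drug + ceiling(dose / comp$vial_mg) * comp$admins_per_cycle *
          comp$vial_price
      }
    }
    p_pfs <- tr$p_pfs[j]; p_pd <- tr$p_pd[j]
    disc <- (1 + econ$discount_rate)^(-(j - 1) * 21 / 365.25)
    total <- total + disc * (drug * p_pfs +
                             ci$hospitalization_per_cycle * (p_pfs + p_pd) +
                             ci$post_progression_per_cycle * p_pd)
  }
  expect_equal(got, total, tolerance = 1e-9)
})

test_that("arm cost is monotone in prices and falls under assistance", {
  cfg <- load_config()
  base <- run_arm(cfg, "whole", "sugemalimab_chemo")$cost
  for (path in c("drugs.sugemalimab.vial_price", "drugs.cisplatin.vial_price",
                 "costs.post_progression_per_cycle",
                 "costs.hospitalization_per_cycle",
                 "adverse_events.risks.sugemalimab_chemo.anemia")) {
    up <- config_set(cfg, path, config_get(cfg, path) * 1.25)
    expect_gt(run_arm(up, "whole", "sugemalimab_chemo")$cost,
              base, label = path)
  }
  pap_cost <- run_arm(cfg, "pap", "sugemalimab_chemo")$cost
  expect_lt(pap_cost, base)
  # control arm holds no gated drug: identical with and without the schedule
  expect_equal(run_arm(cfg, "pap", "chemo")$cost,
               run_arm(cfg, "whole", "chemo")$cost)
  # zero prices zero the arm cost once adverse events are also zeroed
  zero <- cfg
  for (d in names(zero$drugs))
    zero <- config_set(zero, paste0("drugs.", d, ".vial_price"), 0)
  zero <- config_set(zero, "costs.post_progression_per_cycle", 0)
  zero <- config_set(zero, "costs.hospitalization_per_cycle", 0)
  for (arm in names(zero$adverse_events$risks))
    for (ae in names(zero$adverse_events$risks[[arm]]))
      zero <- config_set(zero, paste0("adverse_events.risks.", arm, ".", ae), 0)
  expect_identical(run_arm(zero, "whole", "sugemalimab_chemo")$cost, 0)
})
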