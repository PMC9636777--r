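test_that("index events take the earliest qualifying source with basis", {
  tb <- blank_tables()
  ## diagnosis day 10, qualifying culture day 3 -> culture basis
  tb <- add_patient(tb, "a", index = IDX + 10, basis = "diagnosis_code")
  tb$cultures[patient_id == "a", `:=`(collection_date = IDX + 3,
                                      cfu_per_ml = 1e5)]
  ## culture at 1e3 CFU only, no diagnosis code -> no index event
  tb <- add_patient(tb, "b", basis = "culture")
  tb$cultures[patient_id == "b", cfu_per_ml := 1e3]
  ## diagnosis and qualifying culture same day -> both
  tb <- add_patient(tb, "c", basis = "both")
  ev <- identify_index_events(tb$diagnoses, tb$cultures)
  expect_identical(ev[patient_id == "a", basis], "culture")
  expect_identical(ev[patient_id == "a", index_date], IDX + 3)
  expect_false("b" %in% ev$patient_id)
  expect_identical(ev[patient_id == "c", basis], "both")
  ## non-uropathogen organisms never qualify
  tb$cultures[patient_id == "c", organism := "C. albicans"]
  ev2 <- identify_index_events(tb$diagnoses, tb$cultures)
  expect_identical(ev2[patient_id == "c", basis], "diagnosis_code")
  expect_error(identify_index_events(tb$diagnoses, tb$cultures,
                                     list(uti_codes = character(),
                                          uropathogens = "E. coli")),
               "empty")
})

test_that("inclusion enforces sex, age 12, the +/-5-day oral window, panels", {
  tb <- blank_tables()
  tb <- add_patient(tb, "ok")
  tb <- add_patient(tb, "male", sex = "male")
  tb <- add_patient(tb, "young", age = 11)
  tb <- add_patient(tb, "edge5", rx_offset = 5L)   # boundary inclusive
  tb <- add_patient(tb, "edge6", rx_offset = 6L)   # outside window
  tb <- add_patient(tb, "ivonly", rx_route = "iv")
  tb <- add_patient(tb, "nopanel", panel = NULL)
  ev <- identify_index_events(tb$diagnoses, tb$cultures)
  inc <- apply_inclusion(ev, tb$patients, tb$prescriptions, tb$cultures)
  expect_setequal(inc$events$patient_id, c("ok", "edge5"))
  att <- inc$attrition
  expect_identical(att[filter == "not_female", n_dropped], 1L)
  expect_identical(att[filter == "age_lt_12", n_dropped], 1L)
  expect_identical(att[filter == "no_oral_antibiotic_within_5d", n_dropped],
                   2L)  # edge6 and ivonly
  expect_identical(att[filter == "no_susceptibility_panel", n_dropped], 1L)
})

test_that("initial therapy is the earliest oral order, ties deterministic", {
  tb <- blank_tables()
  tb <- add_patient(tb, "p", rx_drug = "sxt", rx_dur = 3L, rx_offset = 2L)
  tb$prescriptions <- rbind(tb$prescriptions, data.table(
    patient_id = "p", order_date = IDX + 1L, drug = "nitrofurantoin",
    route = "oral", duration_days = 5L))
  ev <- identify_index_events(tb$diagnoses, tb$cultures)
  inc <- apply_inclusion(ev, tb$patients, tb$prescriptions, tb$cultures)
  expect_identical(inc$events$initial_drug, "nitrofurantoin")
  expect_identical(inc$events$initial_rx_date, IDX + 1L)
})

test_that("48-hour windows cover index plus two calendar days", {
  mk <- function(offset) {
    tb <- blank_tables()
    tb <- add_patient(tb, "p")
    tb$diagnoses <- rbind(tb$diagnoses, data.table(
      patient_id = "p", date = IDX + offset, code = "R50.9",
      fever_ge_38_3 = TRUE, nausea = FALSE, vomiting = FALSE,
      flank_pain = FALSE, pregnancy_flag = FALSE, catheter_flag = FALSE))
    ev <- identify_index_events(tb$diagnoses, tb$cultures)
    inc <- apply_inclusion(ev, tb$patients, tb$prescriptions, tb$cultures)
    exc <- apply_exclusion(inc$events, tb, cohort_scenario("baseline"))
    nrow(exc$cohort)
  }
  expect_identical(mk(2L), 0L)  # within 48 h -> dropped
  expect_identical(mk(3L), 1L)  # beyond 48 h -> retained
})

test_that("strict scenario drops single-basis patients; loose is a superset", {
  tb <- small_sim(n = 500, seed = 21)
  base <- build_cohort(tb, cohort_scenario("baseline"))
  strict <- build_cohort(tb, cohort_scenario("strict"))
  loose <- build_cohort(tb, cohort_scenario("loose"))
  expect_true(all(strict$cohort$patient_id %in% base$cohort$patient_id))
  expect_true(all(base$cohort$patient_id %in% loose$cohort$patient_id))
  expect_true(all(strict$cohort$basis == "both"))
  n_single <- base$cohort[basis != "both", .N]
  expect_identical(nrow(base$cohort) - nrow(strict$cohort), n_single)
})

test_that("planted exclusion cases drop at exactly their filter", {
  tb <- small_sim(n = 300, seed = 9)
  planted <- all_planted_reasons(3L)
  tb <- inject_exclusion_cases(tb, planted)
  cb <- build_cohort(tb, cohort_scenario("baseline"))
  att <- cb$attrition
  for (r in names(planted)) {
    expect_identical(att[filter == reason_filter_map[[r]], n_dropped], 3L,
                     label = r)
  }
  ## no planted patient survives; no core patient is dropped
  expect_false(any(startsWith(cb$cohort$patient_id, "X_")))
  expect_identical(nrow(cb$cohort), 300L)
})

test_that("conservation and monotonicity hold in every scenario", {
  tb <- small_sim(n = 250, seed = 33)
  tb <- inject_exclusion_cases(tb, c(pregnancy = 4L, iv_initial = 2L))
  for (s in c("baseline", "strict", "loose", "fu30", "fu360",
              "no_prior_infection", "fq_only")) {
    cb <- build_cohort(tb, cohort_scenario(s))
    att <- cb$attrition
    expect_true(all(diff(att$n_remaining) <= 0), label = s)
    expect_identical(att$n_remaining[1],
                     att$n_remaining[nrow(att)] + sum(att$n_dropped),
                     label = s)
    expect_identical(att$n_remaining[nrow(att)], nrow(cb$cohort), label = s)
  }
})

test_that("filters are idempotent and order-invariant over row shuffles", {
  tb <- small_sim(n = 200, seed = 12)
  tb <- inject_exclusion_cases(tb, c(pregnancy = 3L, catheter = 2L))
  cb1 <- build_cohort(tb)
  ## idempotence: re-running exclusion on the surviving cohort drops nothing
  exc2 <- apply_exclusion(cb1$cohort, tb, cohort_scenario("baseline"))
  expect_identical(sum(exc2$attrition$n_dropped), 0L)
  expect_setequal(exc2$cohort$patient_id, cb1$cohort$patient_id)
  ## shuffling input table rows leaves the report unchanged
  tb2 <- tb
  set.seed(99)
  for (nm in c("diagnoses", "prescriptions", "cultures", "encounters")) {
    tb2[[nm]] <- tb2[[nm]][sample(.N)]
  }
  cb2 <- build_cohort(tb2)
  expect_identical(cb1$attrition, cb2$attrition)
  expect_setequal(cb1$cohort$patient_id, cb2$cohort$patient_id)
})

test_that("attrition_waterfall validates its accounting identities", {
  good <- data.table(filter = c("f1", "f2"), n_dropped = c(2L, 1L),
                     n_remaining = c(8L, 7L))
  out <- attrition_waterfall(list(good), 10L)
  expect_identical(out$n_remaining, c(10L, 8L, 7L))
  bad <- data.table(filter = "f1", n_dropped = 1L, n_remaining = 12L)
  expect_error(attrition_waterfall(list(bad), 10L), "monotone")
})
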