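## Per-patient analysis dataset assembly and the sensitivity battery.
## Every scenario re-runs cohort -> classifier -> costs -> matching -> GLM
## from the raw tables; scenarios share no mutable state.

#' Assemble the per-patient analysis dataset for a scenario
#'
#' Runs the cohort waterfall and the rule engine, then attaches
#' demographics, Charlson score, baseline HCRU, and follow-up costs.
#'
#' @param tables EHR table bundle
#' @param scenario a [cohort_scenario()] or scenario name
#' @param code_lists,formulary,fee_schedule configuration
#' @return list with `data` (one row per cohort patient), `attrition`,
#'   `labels`, `scenario`
#' @export
assemble_analysis <- function(tables, scenario = cohort_scenario(),
                              code_lists = default_code_lists(),
                              formulary = default_formulary(),
                              fee_schedule = default_fee_schedule()) {
  if (is.character(scenario)) scenario <- cohort_scenario(scenario)
  cb <- build_cohort(tables, scenario, code_lists, formulary)
  cohort <- cb$cohort
  if (!nrow(cohort)) {
    return(list(data = data.table(), attrition = cb$attrition,
                labels = data.table(), scenario = scenario))
  }
  labels <- classify_treatments(cohort, tables$prescriptions,
                                tables$cultures, tables$allergies,
                                formulary = formulary)
  idx <- cohort[, .(patient_id, index_date)]
  cci <- charlson_score(tables$diagnoses, idx)
  base <- tabulate_hcru(tables$encounters, tables$prescriptions, idx,
                        -scenario$baseline_days, 0L)
  setnames(base, setdiff(names(base), "patient_id"),
           paste0("base_", setdiff(names(base), "patient_id")))
  costs <- compute_costs(tables$encounters, tables$prescriptions, idx,
                         fee_schedule, 0L, scenario$followup_days,
                         indicated_antibiotics(formulary))
  dat <- Reduce(function(a, b) merge(a, b, by = "patient_id"),
                list(cohort[, .(patient_id, index_date, basis, age_at_index,
                                race, ethnicity, insurance, initial_drug)],
                     labels, cci, base, costs))
  dat[, `:=`(
    white = as.integer(race == "white"),
    private_insurance = as.integer(insurance == "private"),
    ns = as.integer(person_level == "not_susceptible"),
    base_outpatient = base_outpatient_clinic + base_outpatient_other +
      base_outpatient_ambulatory_surgery
  )]
  list(data = dat, attrition = cb$attrition, labels = labels,
       scenario = scenario)
}

#' Progression to complicated UTI by arm
#'
#' Proportion of patients with a cUTI-qualifying diagnosis code or symptom
#' flag within the follow-up window, by susceptibility arm, with the risk
#' difference (not-susceptible minus susceptible) and a two-sample
#' proportion test p-value.
#'
#' @param data analysis rows with `patient_id`, `index_date`, `ns`
#' @param diagnoses diagnosis table
#' @param followup_days window length (half-open from index)
#' @param code_lists supplies `cuti_codes`
#' @return list: `p_susceptible`, `p_not_susceptible`, `diff`, `p_value`,
#'   `n` (per-arm counts)
#' @export
cuti_progression <- function(data, diagnoses, followup_days = 180L,
                             code_lists = default_code_lists()) {
  if (!nrow(data) || length(unique(data$ns)) < 2) {
    stop_uticost("cuti_progression needs both susceptibility arms")
  }
  dg <- diagnoses[data[, .(patient_id, index_date)], on = .(patient_id),
                  nomatch = NULL, allow.cartesian = TRUE]
  dg <- dg[date >= index_date & date < index_date + followup_days]
  hit <- dg[code %chin% code_lists$cuti_codes |
              fever_ge_38_3 | nausea | vomiting | flank_pain,
            unique(patient_id)]
  prog <- data$patient_id %chin% hit
  ns <- data$ns == 1
  x <- c(sum(prog[ns]), sum(prog[!ns]))
  n <- c(sum(ns), sum(!ns))
  pv <- if (all(prog) || !any(prog)) 1 else
    suppressWarnings(prop.test(x, n)$p.value)
  list(p_susceptible = x[2] / n[2], p_not_susceptible = x[1] / n[1],
       diff = x[1] / n[1] - x[2] / n[2], p_value = pv,
       n = c(not_susceptible = n[1], susceptible = n[2]))
}

#' Run one sensitivity scenario end to end
#'
#' Cohort construction under the scenario's criteria and follow-up window,
#' treatment adjudication, cost construction, 1:1 propensity matching of
#' not-susceptible versus susceptible patients, adjusted gamma log-link
#' cost contrasts (raw and winsorized at the 98th percentile, all-cause
#' and UTI-related), and the complicated-UTI progression difference —
#' all computed on the matched sample.
#'
#' @param tables EHR table bundle
#' @param scenario scenario name or [cohort_scenario()]
#' @param seed integer seed (matching order)
#' @param caliper logit-scale caliper for [match_1to1()]
#' @param code_lists,formulary,fee_schedule configuration
#' @return one-row `data.table` with scenario name, per-arm sample size,
#'   cUTI risk difference and p-value, and cost differences
#'   (not-susceptible minus susceptible) with p-values for the four
#'   outcome variants; a scenario yielding an empty arm returns a row
#'   flagged `empty_arm` instead of crashing
#' @export
run_scenario <- function(tables, scenario = "baseline", seed = 1L,
                         caliper = NULL,
                         code_lists = default_code_lists(),
                         formulary = default_formulary(),
                         fee_schedule = default_fee_schedule()) {
  if (is.character(scenario)) scenario <- cohort_scenario(scenario)
  asm <- assemble_analysis(tables, scenario, code_lists, formulary,
                           fee_schedule)
  dat <- asm$data
  empty_row <- data.table(
    scenario = scenario$name, n_per_arm = 0L, flag = "empty_arm",
    cuti_diff = NA_real_, cuti_p = NA_real_,
    allcause_diff = NA_real_, allcause_p = NA_real_,
    uti_diff = NA_real_, uti_p = NA_real_,
    allcause_wins_diff = NA_real_, allcause_wins_p = NA_real_,
    uti_wins_diff = NA_real_, uti_wins_p = NA_real_)
  if (!nrow(dat) || length(unique(dat$ns)) < 2) return(empty_row)

  ps <- estimate_propensity(dat, "ns", ps_covariates("susceptibility"))
  mc <- match_1to1(ps$scores, dat$ns == 1, ids = dat$patient_id,
                   caliper = caliper, seed = seed)
  if (!nrow(mc$pairs)) return(empty_row)
  md <- dat[patient_id %chin% c(mc$pairs$treated_id, mc$pairs$control_id)]
  md[, ns_group := factor(ifelse(ns == 1, "not_susceptible", "susceptible"),
                          levels = c("susceptible", "not_susceptible"))]
  adjusters <- c("cci", "base_inpatient", "base_emergency",
                 "base_outpatient", "base_drug_orders")
  contrast <- function(outcome_col, wins) {
    dd <- copy(md)
    if (wins) dd[[outcome_col]] <- winsorize(dd[[outcome_col]], 98)
    res <- fit_cost_model(dd, outcome_col, "ns_group", adjusters)
    est <- res$estimates[group == "not_susceptible"]
    c(diff = est$diff_vs_ref, p = est$p_value)
  }
  ac <- contrast("all_cause_cost", FALSE)
  ut <- contrast("uti_related_cost", FALSE)
  acw <- contrast("all_cause_cost", TRUE)
  utw <- contrast("uti_related_cost", TRUE)
  cp <- cuti_progression(md, tables$diagnoses, scenario$followup_days,
                         code_lists)
  data.table(
    scenario = scenario$name, n_per_arm = nrow(mc$pairs), flag = "",
    cuti_diff = cp$diff, cuti_p = cp$p_value,
    allcause_diff = ac[["diff"]], allcause_p = ac[["p"]],
    uti_diff = ut[["diff"]], uti_p = ut[["p"]],
    allcause_wins_diff = acw[["diff"]], allcause_wins_p = acw[["p"]],
    uti_wins_diff = utw[["diff"]], uti_wins_p = utw[["p"]])
}

#' Run the full sensitivity battery
#'
#' Baseline plus the six variants, each an independent end-to-end re-run
#' from the raw tables for a fixed seed.
#'
#' @inheritParams run_scenario
#' @param scenarios scenario names to run
#' @return `data.table`, one row per scenario (see [run_scenario()])
#' @export
run_sensitivity <- function(tables, seed = 1L,
                            scenarios = c("baseline", "strict", "loose",
                                          "fu30", "fu360",
                                          "no_prior_infection", "fq_only"),
                            ...) {
  rbindlist(lapply(scenarios, function(s)
    run_scenario(tables, s, seed = seed, ...)))
}
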