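## Shared fixture builders: everything is constructed in code at test time.

library(data.table)

IDX <- as.Date("2020-01-01")

## empty skeletons with the canonical columns
blank_tables <- function() {
  list(
    patients = data.table(patient_id = character(), sex = character(),
                          birth_date = as.Date(character()),
                          race = character(), ethnicity = character(),
                          insurance = character(),
                          data_end_date = as.Date(character()),
                          followup_complete = logical()),
    diagnoses = data.table(patient_id = character(),
                           date = as.Date(character()), code = character(),
                           fever_ge_38_3 = logical(), nausea = logical(),
                           vomiting = logical(), flank_pain = logical(),
                           pregnancy_flag = logical(),
                           catheter_flag = logical()),
    encounters = data.table(patient_id = character(),
                            date = as.Date(character()),
                            setting = character(), uti_related = logical()),
    prescriptions = data.table(patient_id = character(),
                               order_date = as.Date(character()),
                               drug = character(), route = character(),
                               duration_days = integer()),
    cultures = data.table(patient_id = character(), culture_id = character(),
                          collection_date = as.Date(character()),
                          organism = character(), cfu_per_ml = numeric(),
                          antibiotic = character(), result = character()),
    allergies = data.table(patient_id = character(), drug = character(),
                           record_date = as.Date(character()))
  )
}

## one eligible patient with configurable perturbations
add_patient <- function(tb, id, sex = "female", age = 30,
                        index = IDX, basis = "both",
                        rx_drug = "nitrofurantoin", rx_dur = 5L,
                        rx_offset = 0L, rx_route = "oral",
                        panel = c(nitrofurantoin = "S", sxt = "S",
                                  ciprofloxacin = "S", amoxicillin = "S"),
                        followup_complete = TRUE) {
  tb$patients <- rbind(tb$patients, data.table(
    patient_id = id, sex = sex, birth_date = index - round(age * 365.25),
    race = "white", ethnicity = "non_hispanic", insurance = "private",
    data_end_date = as.Date("2021-12-31"),
    followup_complete = followup_complete))
  if (basis %in% c("both", "diagnosis_code")) {
    tb$diagnoses <- rbind(tb$diagnoses, data.table(
      patient_id = id, date = index, code = "N39.0", fever_ge_38_3 = FALSE,
      nausea = FALSE, vomiting = FALSE, flank_pain = FALSE,
      pregnancy_flag = FALSE, catheter_flag = FALSE))
  }
  if (!is.null(panel)) {
    tb$cultures <- rbind(tb$cultures, data.table(
      patient_id = id, culture_id = paste0("C-", id),
      collection_date = index, organism = "E. coli",
      cfu_per_ml = if (basis == "diagnosis_code") 5e3 else 1e5,
      antibiotic = names(panel), result = unname(panel)))
  }
  if (!is.null(rx_drug)) {
    tb$prescriptions <- rbind(tb$prescriptions, data.table(
      patient_id = id, order_date = index + rx_offset, drug = rx_drug,
      route = rx_route, duration_days = rx_dur))
  }
  tb
}

## small generated bundle cached per test file
small_sim <- function(n = 600, seed = 42, ...) {
  generate_population(sim_config(n_patients = n, seed = seed, ...))
}

all_planted_reasons <- function(k = 3L) {
  r <- c("male", "underage", "no_oral_rx", "no_culture_panel", "pregnancy",
         "hiv", "prior_antibiotic", "catheter", "cuti_symptom", "iv_initial",
         "complicating_comorbidity", "missing_data")
  setNames(rep(k, length(r)), r)
}

## map of planted reason -> attrition filter id where it must be dropped
reason_filter_map <- c(
  male = "not_female", underage = "age_lt_12",
  no_oral_rx = "no_oral_antibiotic_within_5d",
  no_culture_panel = "no_susceptibility_panel",
  pregnancy = "pregnancy", hiv = "hiv",
  prior_antibiotic = "prior_antibiotic", catheter = "catheter",
  cuti_symptom = "cuti_symptom", iv_initial = "iv_initial",
  complicating_comorbidity = "complicating_comorbidity",
  missing_data = "missing_data"
)

## ---------------------------------------------------------------------------
## Exhaustive truth-table fixture for the rule engine: 216 scenarios
## (initial therapy x allergy history x received-agent susceptibility x
## switch timing x IV exposure), plus an independently written decision
## table. Shared by the unit audit and the acceptance criterion.
## ---------------------------------------------------------------------------
truthtable_fixture <- function() {
  first_line <- c("fosfomycin", "nitrofurantoin", "sxt")
  grid <- CJ(initial = c("nitro5", "nitro7", "cipro7", "two_first"),
             allergy = c("none", "fosfomycin", "all_first"),
             res = c("S", "I", "R"),
             sw = c("none", "day10", "day35"),
             iv = c(FALSE, TRUE))
  grid[, patient_id := sprintf("g%03d", .I)]
  panel_abx <- c("nitrofurantoin", "sxt", "ciprofloxacin", "fosfomycin")
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    g <- grid[i]
    drugs <- switch(g$initial,
                    nitro5 = data.table(drug = "nitrofurantoin",
                                        duration_days = 5L),
                    nitro7 = data.table(drug = "nitrofurantoin",
                                        duration_days = 7L),
                    cipro7 = data.table(drug = "ciprofloxacin",
                                        duration_days = 7L),
                    two_first = data.table(drug = c("nitrofurantoin", "sxt"),
                                           duration_days = c(5L, 3L)))
    rx <- data.table(patient_id = g$patient_id, order_date = IDX,
                     drug = drugs$drug, route = "oral",
                     duration_days = drugs$duration_days)
    if (g$sw != "none") {
      rx <- rbind(rx, data.table(
        patient_id = g$patient_id,
        order_date = IDX + ifelse(g$sw == "day10", 10L, 35L),
        drug = "cephalexin", route = "oral", duration_days = 7L))
    }
    if (g$iv) {
      rx <- rbind(rx, data.table(patient_id = g$patient_id,
                                 order_date = IDX + 2L, drug = "ceftriaxone",
                                 route = "iv", duration_days = 3L))
    }
    panel <- setNames(rep("S", length(panel_abx)), panel_abx)
    panel[drugs$drug[1]] <- g$res   # received (first) agent's result
    cx <- data.table(patient_id = g$patient_id, culture_id = g$patient_id,
                     collection_date = IDX, organism = "E. coli",
                     cfu_per_ml = 1e5, antibiotic = names(panel),
                     result = unname(panel))
    alg_drugs <- switch(g$allergy, none = character(),
                        fosfomycin = "fosfomycin", all_first = first_line)
    alg <- if (length(alg_drugs)) {
      data.table(patient_id = g$patient_id, drug = alg_drugs,
                 record_date = IDX)
    } else NULL
    list(rx = rx, cx = cx, alg = alg)
  })
  rx <- rbindlist(lapply(rows, `[[`, "rx"))
  cx <- rbindlist(lapply(rows, `[[`, "cx"))
  alg <- rbindlist(Filter(Negate(is.null), lapply(rows, `[[`, "alg")))
  if (is.null(alg) || !nrow(alg)) alg <- blank_tables()$allergies
  cohort <- grid[, .(patient_id, index_date = IDX, initial_rx_date = IDX)]

  ## independent decision table, written directly from the definitions
  oracle <- grid[, {
    rec_drugs <- switch(initial, nitro5 = "nitrofurantoin",
                        nitro7 = "nitrofurantoin", cipro7 = "ciprofloxacin",
                        two_first = c("nitrofurantoin", "sxt"))
    rec_ir <- res %in% c("I", "R")   # applies to the first received drug
    alg_set <- switch(allergy, none = character(),
                      fosfomycin = "fosfomycin", all_first = first_line)
    ir_set <- if (rec_ir) rec_drugs[1] else character()
    second_line_initial <- initial == "cipro7"
    escape <- all(first_line %in% union(alg_set, ir_set))
    inapp <- (initial == "two_first") ||
      (second_line_initial && !escape) ||
      any(rec_drugs %in% ir_set) ||
      any(rec_drugs %in% alg_set)
    subopt <- (sw == "day10") || iv || any(rec_drugs %in% ir_set)
    app_flag <- (initial == "nitro5") ||
      (second_line_initial && allergy == "all_first")
    .(o_inapp = inapp, o_subopt = subopt, o_app = app_flag,
      o_ns = rec_ir)
  }, by = patient_id]

  list(cohort = cohort, rx = rx, cx = cx, alg = alg, oracle = oracle)
}

## run the engine on the fixture and merge with the oracle
truthtable_compare <- function() {
  fx <- truthtable_fixture()
  got <- classify_treatments(fx$cohort, fx$rx, fx$cx, fx$alg)
  merge(got, fx$oracle, by = "patient_id")
}
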