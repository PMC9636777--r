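## Guideline rule engine: person-level susceptibility aggregation,
## appropriate / inappropriate / suboptimal adjudication, and the 4-level
## exposure assignment. One vectorized engine serves both the pipeline and
## the per-patient wrappers, so there is a single source of rule logic;
## every true flag carries the ids of the rules that fired.
##
## Rule ids:
##   inapp_two_first_line        >= 2 distinct first-line agents initially
##   inapp_nonrecommended_initial  second/third/other-line initial therapy
##                                 without allergy-or-resistance to every
##                                 first-line agent
##   inapp_resistant_agent       received an agent with an I/R isolate
##   inapp_allergic_agent        received an agent with a recorded allergy
##   subopt_switch               different UTI antibiotic within 28 days
##   subopt_iv                   IV antibiotics during the episode
##   subopt_ns_index             initial/index agent not-susceptible
##   app_first_line_duration     first-line monotherapy, recommended course
##   app_allergy_alternate       first-line allergies, alternate line given

#' Aggregate isolate susceptibility to person level
#'
#' A patient is `not_susceptible` iff any isolate shows an intermediate or
#' resistant result for at least one antibiotic in the uUTI-indicated set;
#' otherwise `susceptible`. Intermediate counts as not-susceptible.
#'
#' @param cultures culture table (long: one row per isolate x antibiotic)
#' @param indicated_set antibiotics counted in the rule, see
#'   [indicated_antibiotics()]
#' @param expected_patients optional ids that must all have a tested panel;
#'   a missing panel is a pipeline-order violation and raises an error
#' @return `data.table` of `patient_id`, `person_level`
#' @export
aggregate_susceptibility <- function(cultures,
                                     indicated_set = indicated_antibiotics(),
                                     expected_patients = NULL) {
  assert_cols(cultures, c("patient_id", "antibiotic", "result"))
  tested <- cultures[!is.na(result) & nzchar(result)]
  if (!is.null(expected_patients)) {
    miss <- setdiff(expected_patients, unique(tested$patient_id))
    if (length(miss)) {
      stop_uticost("patients without a tested susceptibility panel reached ",
                   "the classifier (pipeline-order violation): ",
                   paste(head(miss, 5), collapse = ", "))
    }
    tested <- tested[patient_id %chin% expected_patients]
  }
  out <- tested[, .(
    person_level = if (any(result %chin% c("I", "R") &
                            antibiotic %chin% indicated_set))
      "not_susceptible" else "susceptible"), by = patient_id]
  setorder(out, patient_id)
  out[]
}

#' Assign the four-level exposure group
#'
#' Cross of person-level susceptibility and final treatment adjudication;
#' susceptible + appropriate (`S_app`) is the reference level.
#'
#' @param final_label `appropriate` / `inappropriate_or_suboptimal` vector
#' @param person_level `susceptible` / `not_susceptible` vector
#' @return factor with levels [exposure_levels()]
#' @export
assign_exposure_group <- function(final_label, person_level) {
  stopifnot(length(final_label) == length(person_level))
  ns <- person_level == "not_susceptible"
  app <- final_label == "appropriate"
  factor(ifelse(ns, ifelse(app, "NS_app", "NS_inapp_sub"),
                ifelse(app, "S_app", "S_inapp_sub")),
         levels = exposure_levels())
}

## The engine. cohort needs patient_id, index_date, initial_rx_date.
## Returns one row per cohort patient with flags + fired rule ids.
.classify_engine <- function(cohort, prescriptions, cultures, allergies,
                             formulary, indicated_set,
                             switch_window_days = 28L,
                             allergy_pre_index_only = FALSE) {
  ids <- cohort$patient_id
  if (anyDuplicated(ids)) stop_uticost("cohort has duplicated patient ids")
  first_line <- formulary[line == "first", drug]
  unknown <- setdiff(unique(prescriptions$drug), formulary$drug)
  if (length(unknown)) {
    stop_uticost("drugs absent from formulary: ",
                 paste(unknown, collapse = ", "))
  }

  ## per-patient I/R antibiotic sets (over all isolates)
  sus <- aggregate_susceptibility(cultures, indicated_set,
                                  expected_patients = ids)
  ir <- cultures[result %chin% c("I", "R"),
                 .(ir_set = list(unique(antibiotic))), by = patient_id]
  alg <- copy(allergies)
  if (allergy_pre_index_only) {
    alg <- alg[cohort[, .(patient_id, index_date)], on = .(patient_id),
               nomatch = NULL][record_date <= index_date]
  }
  alg <- alg[, .(allergy_set = list(unique(drug))), by = patient_id]

  ## initial therapy set: oral orders on the initial order date
  rx <- prescriptions[cohort, on = .(patient_id), nomatch = NULL,
                      allow.cartesian = TRUE]
  init <- rx[route == "oral" & order_date == initial_rx_date,
             .(init_drugs = list(unique(drug)),
               init_durs = list(duration_days[!duplicated(drug)])),
             by = patient_id]
  switch_rx <- rx[drug %chin% formulary$drug &
                    order_date > index_date &
                    order_date <= index_date + switch_window_days,
                  .(later_drugs = list(unique(drug))), by = patient_id]
  iv_rx <- rx[route == "iv" & order_date >= index_date - 5L &
                order_date <= index_date + switch_window_days,
              .(has_iv = TRUE), by = patient_id]

  dt <- cohort[, .(patient_id)]
  dt <- Reduce(function(a, b) merge(a, b, by = "patient_id", all.x = TRUE),
               list(dt, sus, ir, alg, init, switch_rx, iv_rx))
  dt[is.na(has_iv), has_iv := FALSE]

  fl_info <- formulary[, .(drug, line, recommended_duration_days)]
  one <- function(init_drugs, init_durs, ir_set, allergy_set, later_drugs,
                  has_iv) {
    ir_set <- ir_set %||% character()
    allergy_set <- allergy_set %||% character()
    later_drugs <- later_drugs %||% character()
    init_drugs <- init_drugs %||% character()
    lines <- fl_info[match(init_drugs, drug), line]
    fired <- character()
    ## -- inappropriate -----------------------------------------------------
    if (sum(init_drugs %chin% first_line) >= 2L) {
      fired <- c(fired, "inapp_two_first_line")
    }
    escape <- all(first_line %chin% union(ir_set, allergy_set))
    if (any(lines %chin% c("second", "third", "other")) && !escape) {
      fired <- c(fired, "inapp_nonrecommended_initial")
    }
    if (any(init_drugs %chin% ir_set)) {
      fired <- c(fired, "inapp_resistant_agent")
    }
    if (any(init_drugs %chin% allergy_set)) {
      fired <- c(fired, "inapp_allergic_agent")
    }
    ## -- suboptimal --------------------------------------------------------
    if (length(setdiff(later_drugs, init_drugs))) {
      fired <- c(fired, "subopt_switch")
    }
    if (isTRUE(has_iv)) fired <- c(fired, "subopt_iv")
    if (any(init_drugs %chin% ir_set)) {
      fired <- c(fired, "subopt_ns_index")
    }
    ## -- appropriate (positive arm of the definition) ----------------------
    if (length(init_drugs) == 1L && identical(lines, "first")) {
      rec <- fl_info[drug == init_drugs, recommended_duration_days]
      if (length(init_durs[[1]]) && !is.na(rec) && init_durs[[1]][1] == rec) {
        fired <- c(fired, "app_first_line_duration")
      }
    }
    if (all(first_line %chin% allergy_set) && length(init_drugs) == 1L &&
        lines[1] %chin% c("second", "third")) {
      fired <- c(fired, "app_allergy_alternate")
    }
    list(fired = list(fired))
  }
  res <- dt[, one(init_drugs[[1]], init_durs[[1]], ir_set[[1]],
                  allergy_set[[1]], later_drugs[[1]], has_iv),
            by = patient_id]
  res[, inappropriate := vapply(fired, function(f)
    any(startsWith(f, "inapp_")), logical(1))]
  res[, suboptimal := vapply(fired, function(f)
    any(startsWith(f, "subopt_")), logical(1))]
  res[, appropriate := vapply(fired, function(f)
    any(startsWith(f, "app_")), logical(1))]
  res <- merge(res, dt[, .(patient_id, person_level)], by = "patient_id")
  res[, final_label := ifelse(!inappropriate & !suboptimal,
                              "appropriate", "inappropriate_or_suboptimal")]
  res[, exposure_group := assign_exposure_group(final_label, person_level)]
  res[, fired_rules := vapply(fired, paste, character(1), collapse = ";")]
  res[, fired := NULL]
  setorder(res, patient_id)
  res[]
}

#' Adjudicate treatments for a cohort
#'
#' Runs the full rule engine over a cohort: person-level susceptibility,
#' the inappropriate rules (two first-line agents; non-recommended initial
#' therapy without the allergy/resistance escape; receipt of an agent with
#' an I/R isolate; receipt of an agent with a recorded allergy), the
#' suboptimal rules (switch to a different UTI antibiotic within 28 days of
#' index; any IV antibiotics during the episode; initial agent
#' not-susceptible), the positive appropriateness definition (first-line
#' monotherapy at the recommended duration, or first-line allergies with an
#' alternate-line agent), the final label (appropriate iff neither
#' inappropriate nor suboptimal), and the 4-level exposure group.
#'
#' @param cohort cohort table from [build_cohort()] (needs `patient_id`,
#'   `index_date`, `initial_rx_date`)
#' @param prescriptions,cultures,allergies EHR tables
#' @param formulary see [default_formulary()]
#' @param indicated_set antibiotics for person-level aggregation
#' @param switch_window_days switch-rule window after index (default 28,
#'   inclusive)
#' @param allergy_pre_index_only if `TRUE`, only allergies recorded on or
#'   before index count (default uses the full history)
#' @return `data.table`: `patient_id`, `appropriate`, `inappropriate`,
#'   `suboptimal`, `person_level`, `final_label`, `exposure_group`,
#'   `fired_rules` (semicolon-joined rule ids)
#' @export
classify_treatments <- function(cohort, prescriptions, cultures, allergies,
                                formulary = default_formulary(),
                                indicated_set = indicated_antibiotics(formulary),
                                switch_window_days = 28L,
                                allergy_pre_index_only = FALSE) {
  assert_cols(cohort, c("patient_id", "index_date", "initial_rx_date"))
  .classify_engine(cohort, prescriptions, cultures, allergies, formulary,
                   indicated_set, switch_window_days, allergy_pre_index_only)
}

## Build a one-patient bundle and run the engine; shared by the
## per-patient wrappers so they exercise the exact pipeline logic.
.classify_one <- function(initial_rx, rx_extra = NULL, panel = character(),
                          allergy_drugs = character(),
                          formulary = default_formulary(),
                          indicated_set = indicated_antibiotics(formulary)) {
  idx <- as.Date("2020-01-01")
  initial_rx <- as.data.table(initial_rx)
  rx <- data.table(patient_id = "p1", order_date = idx,
                   drug = initial_rx$drug, route = "oral",
                   duration_days = as.integer(initial_rx$duration_days))
  if (!is.null(rx_extra) && nrow(rx_extra)) {
    rx <- rbind(rx, data.table(patient_id = "p1",
                               order_date = idx + rx_extra$day,
                               drug = rx_extra$drug, route = rx_extra$route,
                               duration_days = 3L))
  }
  cx <- data.table(patient_id = "p1", culture_id = "c1",
                   collection_date = idx, organism = "E. coli",
                   cfu_per_ml = 1e5,
                   antibiotic = if (length(panel)) names(panel) else
                     indicated_set[1],
                   result = if (length(panel)) unname(panel) else "S")
  alg <- data.table(patient_id = rep("p1", length(allergy_drugs)),
                    drug = allergy_drugs, record_date = idx)
  cohort <- data.table(patient_id = "p1", index_date = idx,
                       initial_rx_date = idx)
  .classify_engine(cohort, rx, cx, alg, formulary, indicated_set)
}

.split_rules <- function(res, prefix) {
  f <- strsplit(res$fired_rules, ";", fixed = TRUE)[[1]]
  f[startsWith(f, prefix)]
}

#' Classify a single patient's initial therapy as inappropriate
#'
#' Per-patient wrapper around the rule engine, used for decision-table
#' audits. Inappropriate iff: two or more distinct first-line agents
#' initially; a second/third/other-line initial agent while the patient is
#' neither allergic nor resistant to every first-line option; any received
#' agent with an I/R isolate; or any received agent with a recorded
#' allergy.
#'
#' @param initial_rx data.frame of the initial therapy set: columns `drug`,
#'   `duration_days`
#' @param allergies character vector of drugs with allergy records
#' @param susceptibility named character vector, antibiotic -> `S`/`I`/`R`
#' @param formulary see [default_formulary()]
#' @return list with `flag` (logical) and `fired` (rule ids)
#' @export
classify_inappropriate <- function(initial_rx, allergies = character(),
                                   susceptibility = character(),
                                   formulary = default_formulary()) {
  res <- .classify_one(initial_rx, panel = susceptibility,
                       allergy_drugs = allergies, formulary = formulary)
  list(flag = res$inappropriate, fired = .split_rules(res, "inapp_"))
}

#' Classify a single patient's treatment course as suboptimal
#'
#' Suboptimal iff a different UTI antibiotic is ordered within 28 days
#' after index, any IV antibiotic is given during the episode, or the
#' initial agent has an I/R isolate.
#'
#' @inheritParams classify_inappropriate
#' @param rx_history data.frame of post-index orders: columns `drug`,
#'   `day` (offset from index), `route`
#' @param susceptibility named character vector, antibiotic -> `S`/`I`/`R`
#' @return list with `flag` and `fired`
#' @export
classify_suboptimal <- function(rx_history, initial_rx,
                                susceptibility = character(),
                                formulary = default_formulary()) {
  res <- .classify_one(initial_rx, rx_extra = as.data.table(rx_history),
                       panel = susceptibility, formulary = formulary)
  list(flag = res$suboptimal, fired = .split_rules(res, "subopt_"))
}

#' Classify a single patient's initial therapy as appropriate
#'
#' The positive arm of the definition: first-line monotherapy at exactly
#' the recommended duration, or recorded allergies to all first-line agents
#' with a single alternate-line agent prescribed. The cohort-level final
#' label additionally requires not-inappropriate and not-suboptimal.
#'
#' @inheritParams classify_inappropriate
#' @return list with `flag` and `fired`
#' @export
classify_appropriate <- function(initial_rx, allergies = character(),
                                 formulary = default_formulary()) {
  res <- .classify_one(initial_rx, allergy_drugs = allergies,
                       formulary = formulary)
  list(flag = res$appropriate, fired = .split_rules(res, "app_"))
}

#' Classification accounting
#'
#' Counts and percentages (half-up, 1 decimal) for suboptimal,
#' inappropriate, suboptimal-or-inappropriate, suboptimal-and-inappropriate
#' and appropriate patients. Appropriate is the complement of the union, so
#' the table always satisfies the inclusion–exclusion identity.
#'
#' @param labels classifier output ([classify_treatments()]) or any table
#'   with logical `suboptimal` and `inappropriate` columns
#' @return `data.table` of `category`, `n`, `pct`
#' @export
classification_summary <- function(labels) {
  if (!nrow(labels)) stop_uticost("empty cohort")
  n <- nrow(labels)
  s <- labels$suboptimal
  i <- labels$inappropriate
  cnt <- c(suboptimal = sum(s), inappropriate = sum(i),
           suboptimal_or_inappropriate = sum(s | i),
           suboptimal_and_inappropriate = sum(s & i),
           appropriate = sum(!s & !i))
  data.table(category = names(cnt), n = as.integer(cnt),
             pct = pct(as.numeric(cnt), n))
}

#' Charlson comorbidity index
#'
#' Weighted sum over the distinct Charlson categories present strictly
#' before the index date, using configurable weights and an ICD-prefix map.
#'
#' @param diagnoses diagnosis table
#' @param index_dates `data.table` of `patient_id`, `index_date`
#' @param charlson list of `weights` and `code_map`, see
#'   [default_charlson()]
#' @return `data.table` of `patient_id`, `cci` (0 for patients with no
#'   mapped codes)
#' @export
charlson_score <- function(diagnoses, index_dates,
                           charlson = default_charlson()) {
  assert_cols(index_dates, c("patient_id", "index_date"))
  cm <- charlson$code_map
  bad <- setdiff(cm$category, names(charlson$weights))
  if (length(bad)) {
    stop_uticost("unknown comorbidity categories in code map: ",
                 paste(bad, collapse = ", "))
  }
  dx <- diagnoses[index_dates, on = .(patient_id), nomatch = NULL,
                  allow.cartesian = TRUE][date < index_date]
  if (nrow(dx)) {
    pref <- cm$prefix
    cat_of <- function(code) {
      hit <- which(startsWith(code, pref))
      if (length(hit)) cm$category[hit[1]] else NA_character_
    }
    dx[, category := vapply(code, cat_of, character(1))]
    sc <- dx[!is.na(category),
             .(cci = sum(charlson$weights[unique(category)])),
             by = patient_id]
  } else {
    sc <- data.table(patient_id = character(), cci = integer())
  }
  out <- merge(index_dates[, .(patient_id)], sc, by = "patient_id",
               all.x = TRUE)
  out[is.na(cci), cci := 0L]
  setorder(out, patient_id)
  out[]
}
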