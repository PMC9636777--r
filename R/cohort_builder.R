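## Cohort construction: index-event identification and the eligibility
## waterfall. Filters run in a fixed, declared order and every drop is
## recorded in an attrition report; nothing is removed silently.

#' Analysis scenario definitions
#'
#' Bundles the criteria switches used by the sensitivity battery:
#' `baseline` (180-day follow-up, full exclusion list), `strict` (baseline
#' plus the requirement that the index event has both a diagnosis code and
#' a qualifying culture), `loose` (reduced exclusion list: pregnancy,
#' catheter, IV initial therapy, complicating comorbidity), `fu30` /
#' `fu360` (30- and 360-day follow-up; `fu360` additionally requires 360
#' days of data availability), `no_prior_infection` (baseline plus a
#' prior-infection exclusion) and `fq_only` (baseline restricted to index
#' fluoroquinolone recipients).
#'
#' @param name one of `baseline`, `strict`, `loose`, `fu30`, `fu360`,
#'   `no_prior_infection`, `fq_only`
#' @return list of class `cohort_scenario` with `name`, `followup_days`,
#'   `baseline_days`, `exclusions` (ordered filter ids),
#'   `require_both_basis`
#' @export
cohort_scenario <- function(name = c("baseline", "strict", "loose", "fu30",
                                     "fu360", "no_prior_infection",
                                     "fq_only")) {
  name <- match.arg(name)
  full <- c("pregnancy", "hiv", "prior_antibiotic", "catheter",
            "cuti_symptom", "iv_initial", "complicating_comorbidity",
            "missing_data")
  sc <- list(name = name, followup_days = 180L, baseline_days = 180L,
             exclusions = full, require_both_basis = FALSE)
  if (name == "strict") sc$require_both_basis <- TRUE
  if (name == "loose") {
    sc$exclusions <- c("pregnancy", "catheter", "iv_initial",
                       "complicating_comorbidity")
  }
  if (name == "fu30") sc$followup_days <- 30L
  if (name == "fu360") {
    sc$followup_days <- 360L
    sc$exclusions <- c(full, "insufficient_followup")
  }
  if (name == "no_prior_infection") {
    sc$exclusions <- c(full, "prior_infection")
  }
  if (name == "fq_only") {
    sc$exclusions <- c(full, "non_fluoroquinolone_initial")
  }
  structure(sc, class = "cohort_scenario")
}

#' Identify index uUTI events
#'
#' The index date is the earliest of a patient's first uUTI-coded diagnosis
#' and first urine culture with >= 1e4 CFU/mL of a listed uropathogen; the
#' basis records which source(s) defined it (`diagnosis_code`, `culture`,
#' or `both` on a tie). Patients with neither qualifying event simply yield
#' no index event.
#'
#' @param diagnoses,cultures EHR tables
#' @param code_lists list with `uti_codes` and `uropathogens`, see
#'   [default_code_lists()]
#' @return `data.table` with one row per indexed patient: `patient_id`,
#'   `index_date`, `basis`
#' @export
identify_index_events <- function(diagnoses, cultures,
                                  code_lists = default_code_lists()) {
  assert_cols(diagnoses, c("patient_id", "date", "code"))
  assert_cols(cultures, c("patient_id", "collection_date", "organism",
                          "cfu_per_ml"))
  if (!length(code_lists$uti_codes)) stop_uticost("empty uUTI code list")
  if (!length(code_lists$uropathogens)) stop_uticost("empty uropathogen list")

  dx <- diagnoses[code %chin% code_lists$uti_codes,
                  .(dx_date = min(date)), by = patient_id]
  cx <- cultures[cfu_per_ml >= 1e4 & organism %chin% code_lists$uropathogens,
                 .(cx_date = min(collection_date)), by = patient_id]
  ev <- merge(dx, cx, by = "patient_id", all = TRUE)
  ev[, index_date := pmin(dx_date, cx_date, na.rm = TRUE)]
  ev[, basis := fifelse(!is.na(dx_date) & !is.na(cx_date) &
                          dx_date == cx_date, "both",
                 fifelse(!is.na(dx_date) &
                           (is.na(cx_date) | dx_date < cx_date),
                         "diagnosis_code", "culture"))]
  setorder(ev, patient_id)
  ev[, .(patient_id, index_date, basis)]
}

## earliest qualifying oral order in [index-5, index+5]; ties broken by
## order date, then table row order, then drug id (logged as deterministic)
.resolve_initial_rx <- function(events, prescriptions) {
  rx <- copy(prescriptions)[, rx_row := .I]
  cand <- rx[events, on = .(patient_id), nomatch = NULL, allow.cartesian = TRUE]
  cand <- cand[route == "oral" & order_date >= index_date - 5L &
                 order_date <= index_date + 5L]
  if (!nrow(cand)) {
    return(data.table(patient_id = character(),
                      initial_rx_date = as.Date(character()),
                      initial_drug = character(),
                      initial_duration = integer()))
  }
  setorder(cand, patient_id, order_date, rx_row, drug)
  cand[, head(.SD, 1L), by = patient_id][
    , .(patient_id, initial_rx_date = order_date, initial_drug = drug,
        initial_duration = duration_days)]
}

#' Apply inclusion criteria
#'
#' Retains patients who are female, aged >= 12 years at index, have at
#' least one oral antibiotic order within +/- 5 days of index (earliest
#' such order becomes the initial therapy; both endpoints inclusive), and
#' have at least one culture with a non-empty susceptibility panel.
#'
#' @param index_events output of [identify_index_events()]
#' @param patients,prescriptions,cultures EHR tables
#' @return list with `events` (index events augmented with `age_at_index`,
#'   `initial_rx_date`, `initial_drug`, `initial_duration`) and
#'   `attrition` (`data.table` of `filter`, `n_dropped`, `n_remaining`)
#' @export
apply_inclusion <- function(index_events, patients, prescriptions, cultures) {
  assert_cols(patients, c("patient_id", "sex", "birth_date"))
  ev <- merge(index_events, patients, by = "patient_id")
  ev[, age_at_index := as.numeric(index_date - birth_date) / 365.25]
  att <- list()
  step <- function(ev, keep, label) {
    att[[label]] <<- data.table(filter = label, n_dropped = sum(!keep),
                                n_remaining = sum(keep))
    ev[keep]
  }
  ev <- step(ev, ev$sex == "female", "not_female")
  ev <- step(ev, ev$age_at_index >= 12, "age_lt_12")
  init <- .resolve_initial_rx(ev, prescriptions)
  ev <- merge(ev, init, by = "patient_id", all.x = TRUE)
  ev <- step(ev, !is.na(ev$initial_drug), "no_oral_antibiotic_within_5d")
  tested <- unique(cultures[!is.na(antibiotic) & nzchar(antibiotic) &
                              !is.na(result), patient_id])
  ev <- step(ev, ev$patient_id %chin% tested, "no_susceptibility_panel")
  list(events = ev, attrition = rbindlist(att))
}

## per-filter drop predicates; each returns the logical "drop" vector
.exclusion_flag <- function(id, ev, tables, scenario, code_lists, formulary) {
  dg <- tables$diagnoses
  px <- tables$prescriptions
  flag_ids <- function(sub) ev$patient_id %chin% unique(sub$patient_id)
  within_48h <- function(d, idx) d >= idx & d <= idx + 2L
  j <- function(sub) {
    m <- sub[ev, on = .(patient_id), nomatch = NULL]
    m
  }
  switch(id,
    basis_not_both = ev$basis != "both",
    pregnancy = {
      m <- j(dg[pregnancy_flag == TRUE])
      flag_ids(m[date == index_date])
    },
    hiv = flag_ids(j(dg[code %chin% code_lists$hiv_codes])[date <= index_date]),
    prior_antibiotic = {
      m <- j(px)
      flag_ids(m[order_date >= index_date - 180L &
                   order_date <= index_date - 6L])
    },
    catheter = {
      m <- j(dg[catheter_flag == TRUE])
      flag_ids(m[within_48h(date, index_date)])
    },
    cuti_symptom = {
      m <- j(dg[fever_ge_38_3 | nausea | vomiting | flank_pain])
      flag_ids(m[within_48h(date, index_date)])
    },
    iv_initial = {
      m <- j(px[route == "iv"])
      flag_ids(m[order_date >= index_date - 5L & order_date <= index_date + 5L &
                   order_date < initial_rx_date])
    },
    complicating_comorbidity =
      flag_ids(j(dg[code %chin% code_lists$complicating_codes])[
        date <= index_date]),
    missing_data = {
      fc <- tables$patients[, .(patient_id, followup_complete)]
      !fc[ev, on = .(patient_id), followup_complete]
    },
    insufficient_followup = {
      de <- tables$patients[, .(patient_id, data_end_date)]
      end <- de[ev, on = .(patient_id), data_end_date]
      ev$index_date + scenario$followup_days > end
    },
    prior_infection = {
      m <- j(dg[code %chin% code_lists$infection_codes])
      flag_ids(m[date >= index_date - 180L & date <= index_date - 1L])
    },
    non_fluoroquinolone_initial = {
      fq <- formulary[class == "fluoroquinolone", drug]
      !ev$initial_drug %chin% fq
    },
    stop_uticost("unknown exclusion filter: ", id)
  )
}

#' Apply exclusion criteria
#'
#' Drops patients in the scenario's fixed filter order: pregnancy at index;
#' HIV/AIDS diagnosis; antibiotic use in the 180-to-6 days before index;
#' urinary catheter at index or within 48 h; any complicated-UTI symptom
#' (fever >= 38.3 C, nausea, vomiting, flank pain) at index or within 48 h;
#' IV antibiotics before the first oral order; complicating comorbidity;
#' missing follow-up data — plus the scenario's extra switches. 48-hour
#' windows are the index date and the following two calendar dates.
#'
#' @param events inclusion-filtered events from [apply_inclusion()]
#' @param tables the EHR table bundle
#' @param scenario a [cohort_scenario()]
#' @param code_lists,formulary configuration, see [default_code_lists()]
#'   and [default_formulary()]
#' @return list with `cohort` (surviving events) and `attrition`
#' @export
apply_exclusion <- function(events, tables, scenario = cohort_scenario(),
                            code_lists = default_code_lists(),
                            formulary = default_formulary()) {
  stopifnot(inherits(scenario, "cohort_scenario"))
  filters <- scenario$exclusions
  if (scenario$require_both_basis) filters <- c("basis_not_both", filters)
  ev <- copy(events)
  att <- vector("list", length(filters))
  for (i in seq_along(filters)) {
    id <- filters[[i]]
    drop <- .exclusion_flag(id, ev, tables, scenario, code_lists, formulary)
    drop[is.na(drop)] <- FALSE
    att[[i]] <- data.table(filter = id, n_dropped = sum(drop),
                           n_remaining = sum(!drop))
    ev <- ev[!drop]
  }
  list(cohort = ev, attrition = rbindlist(att))
}

#' Assemble the attrition waterfall
#'
#' Concatenates per-stage attrition reports, prepends the initial count and
#' validates the accounting identities: counts are monotone non-increasing
#' and initial n equals final n plus the sum of drops.
#'
#' @param reports list of attrition `data.table`s in execution order
#' @param n_initial number of patients entering the first filter
#' @return `data.table` of `filter`, `n_dropped`, `n_remaining` (first row
#'   is `identified` with the initial count)
#' @export
attrition_waterfall <- function(reports, n_initial) {
  rep_all <- rbindlist(reports)
  out <- rbind(data.table(filter = "identified", n_dropped = 0L,
                          n_remaining = as.integer(n_initial)), rep_all)
  if (any(diff(out$n_remaining) > 0)) {
    stop_uticost("attrition counts are not monotone non-increasing")
  }
  if (n_initial != out[.N, n_remaining] + sum(out$n_dropped)) {
    stop_uticost("attrition accounting identity violated")
  }
  out[]
}

#' Run the full cohort waterfall for a scenario
#'
#' Convenience wrapper: index identification, inclusion, exclusion, and the
#' assembled waterfall.
#'
#' @inheritParams apply_exclusion
#' @param tables EHR table bundle (list with the six tables)
#' @return list with `cohort`, `attrition`, `n_initial`
#' @export
build_cohort <- function(tables, scenario = cohort_scenario(),
                         code_lists = default_code_lists(),
                         formulary = default_formulary()) {
  idx <- identify_index_events(tables$diagnoses, tables$cultures, code_lists)
  inc <- apply_inclusion(idx, tables$patients, tables$prescriptions,
                         tables$cultures)
  exc <- apply_exclusion(inc$events, tables, scenario, code_lists, formulary)
  list(cohort = exc$cohort,
       attrition = attrition_waterfall(list(inc$attrition, exc$attrition),
                                       nrow(idx)),
       n_initial = nrow(idx))
}
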