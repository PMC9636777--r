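## Synthetic EHR generator.
##
## Emits the six flat tables the pipeline consumes (patients, diagnoses,
## encounters, prescriptions, cultures, allergies) plus a ground-truth
## record, with the statistical structure the analysis assumes: every core
## patient is an eligible uUTI case; susceptibility, prescribing quality
## and follow-up costs are planted per the configured probabilities and
## group multipliers; confounding ties not-susceptibility to age, race and
## insurance so propensity matching has real work to do.

.panel_antibiotics <- function() {
  c("nitrofurantoin", "sxt", "ciprofloxacin", "levofloxacin",
    "amoxicillin", "cephalexin")
}

## intercept a such that mean(plogis(a + lp)) == target
.solve_logit_intercept <- function(lp, target) {
  if (target <= 0) return(-Inf)
  if (target >= 1) return(Inf)
  f <- function(a) mean(plogis(a + lp)) - target
  uniroot(f, c(-30, 30), tol = 1e-10)$root
}

#' Generate a synthetic uUTI EHR population
#'
#' Every generated patient is female, at least 12 years old at index, has
#' an index uUTI event identifiable by diagnosis code and/or qualifying
#' culture (>= 1e4 CFU/mL of a uropathogen), at least one oral antibiotic
#' order within +/- 5 days of index, and a culture with an S/I/R panel —
#' i.e. the core population passes the eligibility waterfall by
#' construction. Exclusion-bound patients are added separately by
#' [inject_exclusion_cases()].
#'
#' Follow-up costs are planted as gamma draws with mean
#' `base_cost * group_cost_multipliers[group]`, then realised as encounter
#' counts (Poisson given the gamma draw) priced by the fee schedule, so the
#' expected per-group cost is exact while the tables stay count-shaped.
#'
#' @param config a [sim_config()]
#' @param fee_schedule fee schedule used to convert planted cost targets to
#'   encounter counts; must match the one used downstream for exact
#'   calibration
#' @return list of class `synthetic_ehr` with elements `patients`,
#'   `diagnoses`, `encounters`, `prescriptions`, `cultures`, `allergies`,
#'   `ground_truth`, `config`
#' @export
generate_population <- function(config, fee_schedule = default_fee_schedule()) {
  if (!inherits(config, "sim_config")) {
    stop_uticost("config must be built with sim_config()")
  }
  withr::local_seed(config$seed)
  n <- config$n_patients
  pid <- sprintf("P%06d", seq_len(n))

  ## demographics ----------------------------------------------------------
  index_date <- as.Date("2017-01-01") +
    sample.int(as.integer(as.Date("2019-06-30") - as.Date("2017-01-01")) + 1L,
               n, replace = TRUE) - 1L
  age <- rnorm(n, config$age_mean, config$age_sd)
  while (any(age < 12)) {
    i <- age < 12
    age[i] <- rnorm(sum(i), config$age_mean, config$age_sd)
  }
  race <- sample(names(config$race_probs), n, TRUE, config$race_probs)
  ethnicity <- sample(names(config$ethnicity_probs), n, TRUE,
                      config$ethnicity_probs)
  insurance <- sample(names(config$insurance_probs), n, TRUE,
                      config$insurance_probs)
  birth_date <- index_date - round(age * 365.25)

  ## planted susceptibility & prescribing quality --------------------------
  cf <- config$confounding
  lp <- cf[["age"]] * (age - config$age_mean) +
    cf[["white"]] * (race == "white") +
    cf[["private"]] * (insurance == "private")
  a0 <- .solve_logit_intercept(lp, config$prevalence_not_susceptible)
  p_ns <- if (is.finite(a0)) plogis(a0 + lp) else as.numeric(a0 > 0)
  ns <- rbinom(n, 1L, p_ns) == 1L
  inapp <- rbinom(n, 1L, ifelse(ns, config$p_inappropriate_given_ns,
                                config$p_inappropriate_given_s)) == 1L
  grp <- factor(ifelse(ns,
                       ifelse(inapp, "NS_inapp_sub", "NS_app"),
                       ifelse(inapp, "S_inapp_sub", "S_app")),
                levels = exposure_levels())

  patients <- data.table(
    patient_id = pid, sex = "female", birth_date = birth_date,
    race = race, ethnicity = ethnicity, insurance = insurance,
    data_end_date = as.Date("2020-03-31"), followup_complete = TRUE
  )

  ## index basis & cultures ------------------------------------------------
  basis <- sample(names(config$basis_probs), n, TRUE, config$basis_probs)
  organism <- sample(c("E. coli", "K. pneumoniae", "P. mirabilis"), n, TRUE,
                     c(0.80, 0.12, 0.08))
  cfu <- ifelse(basis == "diagnosis_code", 5e3, 1e5)  # dx-only: non-qualifying
  abx <- .panel_antibiotics()
  cultures <- data.table(
    patient_id = rep(pid, each = length(abx)),
    culture_id = rep(sprintf("C-%s", pid), each = length(abx)),
    collection_date = rep(index_date, each = length(abx)),
    organism = rep(organism, each = length(abx)),
    cfu_per_ml = rep(cfu, each = length(abx)),
    antibiotic = rep(abx, times = n),
    result = "S"
  )
  ## not-susceptible patients: plant I/R on amoxicillin (uUTI-indicated but
  ## never prescribed here), so person-level status flips without touching
  ## the received-drug rules
  planted_res <- data.table(patient_id = pid[ns],
                            result = ifelse(runif(sum(ns)) < 0.3, "I", "R"))
  cultures[planted_res, on = .(patient_id),
           result := ifelse(antibiotic == "amoxicillin", i.result, result)]

  ## diagnoses -------------------------------------------------------------
  cl <- default_code_lists()
  dx_list <- list()
  has_dx <- basis != "culture"
  dx_list$index <- data.table(
    patient_id = pid[has_dx], date = index_date[has_dx],
    code = sample(cl$uti_codes, sum(has_dx), TRUE, c(0.7, 0.3))
  )
  ## baseline Charlson comorbidities (independent Bernoulli per category)
  chmap <- default_charlson()$code_map
  for (cat in names(config$comorbidity_probs)) {
    hit <- runif(n) < config$comorbidity_probs[[cat]]
    if (!any(hit)) next
    dx_list[[cat]] <- data.table(
      patient_id = pid[hit],
      date = index_date[hit] - sample(30:365, sum(hit), TRUE),
      code = chmap[category == cat, prefix]
    )
  }
  ## prior (non-UTI) infections, used by the sensitivity filter
  prior_inf <- runif(n) < 0.08
  if (any(prior_inf)) {
    dx_list$prior_infection <- data.table(
      patient_id = pid[prior_inf],
      date = index_date[prior_inf] - sample(30:170, sum(prior_inf), TRUE),
      code = sample(cl$infection_codes, sum(prior_inf), TRUE)
    )
  }
  ## progression to complicated UTI during follow-up
  cuti <- runif(n) < ifelse(ns, config$p_cuti_ns, config$p_cuti_s)
  if (any(cuti)) {
    lag_max <- min(60L, config$followup_days - 1L)
    dx_list$cuti <- data.table(
      patient_id = pid[cuti],
      date = index_date[cuti] + sample(3:max(3L, lag_max), sum(cuti), TRUE),
      code = cl$cuti_codes[[1L]]
    )
  }
  diagnoses <- rbindlist(dx_list, use.names = TRUE)
  diagnoses[, `:=`(fever_ge_38_3 = FALSE, nausea = FALSE, vomiting = FALSE,
                   flank_pain = FALSE, pregnancy_flag = FALSE,
                   catheter_flag = FALSE)]

  ## prescriptions ---------------------------------------------------------
  ## appropriate: first-line monotherapy at the recommended duration;
  ## inappropriate-or-suboptimal: fluoroquinolone initial therapy (fires the
  ## non-recommended-initial rule), ~30% also switch agents within 28 days
  first_drug <- ifelse(inapp, "ciprofloxacin",
                       ifelse(runif(n) < 0.76, "nitrofurantoin", "sxt"))
  first_dur <- ifelse(first_drug == "ciprofloxacin", 7L,
                      ifelse(first_drug == "nitrofurantoin", 5L, 3L))
  rx_list <- list(initial = data.table(
    patient_id = pid, order_date = index_date, drug = first_drug,
    route = "oral", duration_days = as.integer(first_dur)
  ))
  switch_ix <- inapp & runif(n) < 0.30
  if (any(switch_ix)) {
    rx_list$switch <- data.table(
      patient_id = pid[switch_ix],
      order_date = index_date[switch_ix] + sample(3:20, sum(switch_ix), TRUE),
      drug = "sxt", route = "oral", duration_days = 3L
    )
  }
  prescriptions <- rbindlist(rx_list, use.names = TRUE)

  ## allergies: recorded against fosfomycin (first-line, never prescribed
  ## here) so the allergy table is populated without flipping any rule
  alg <- runif(n) < config$allergy_prevalence
  allergies <- data.table(
    patient_id = pid[alg], drug = "fosfomycin", record_date = index_date[alg]
  )

  ## encounters ------------------------------------------------------------
  mult <- config$group_cost_multipliers[as.character(grp)]
  shape <- config$cost_shape
  x_uti <- rgamma(n, shape, scale = config$base_cost_uti * mult / shape)
  x_oth <- rgamma(n, shape,
                  scale = (config$base_cost_allcause - config$base_cost_uti) *
                    mult / shape)
  fee <- fee_schedule$setting_cost
  enc_list <- list(
    .enc_block(pid, index_date, rpois(n, x_uti / fee[["outpatient_clinic"]]),
               "outpatient_clinic", TRUE, 0L, config$followup_days - 1L),
    .enc_block(pid, index_date, rpois(n, x_oth / fee[["outpatient_other"]]),
               "outpatient_other", FALSE, 0L, config$followup_days - 1L),
    ## baseline utilization; clinic rate drifts with age so the propensity
    ## covariates are genuinely informative
    .enc_block(pid, index_date,
               rpois(n, pmax(0.2, 0.9 + 0.004 * (age - config$age_mean))),
               "outpatient_clinic", FALSE, -config$baseline_days, -1L),
    .enc_block(pid, index_date, rpois(n, 0.10), "outpatient_other", FALSE,
               -config$baseline_days, -1L),
    .enc_block(pid, index_date, rpois(n, 0.05 + 0.03 * ns), "emergency",
               FALSE, -config$baseline_days, -1L),
    .enc_block(pid, index_date, rpois(n, 0.004 + 0.008 * ns), "inpatient",
               FALSE, -config$baseline_days, -1L),
    .enc_block(pid, index_date, rpois(n, 0.012),
               "outpatient_ambulatory_surgery", FALSE,
               -config$baseline_days, -1L),
    ## sparse late activity beyond the core follow-up window
    .enc_block(pid, index_date, rpois(n, 0.15), "outpatient_clinic", FALSE,
               config$followup_days, 359L)
  )
  encounters <- rbindlist(enc_list, use.names = TRUE)
  setorder(encounters, patient_id, date, setting)

  ground_truth <- data.table(
    patient_id = pid, index_date = index_date, true_ns = as.integer(ns),
    true_inapp_sub = as.integer(inapp), true_group = as.character(grp),
    expected_cost_allcause = config$base_cost_allcause * mult,
    expected_cost_uti = config$base_cost_uti * mult,
    cuti_event = as.integer(cuti), planted_reason = NA_character_
  )

  structure(list(patients = patients, diagnoses = diagnoses,
                 encounters = encounters, prescriptions = prescriptions,
                 cultures = cultures, allergies = allergies,
                 ground_truth = ground_truth, config = config),
            class = "synthetic_ehr")
}

## expand per-patient counts into encounter rows with uniform dates in
## [index + lo, index + hi]
.enc_block <- function(pid, index_date, counts, setting, uti, lo, hi) {
  tot <- if (lo > hi) 0L else sum(counts)
  if (tot == 0L) {
    return(data.table(patient_id = character(), date = as.Date(character()),
                      setting = character(), uti_related = logical()))
  }
  data.table(
    patient_id = rep(pid, counts),
    date = rep(index_date, counts) + sample(lo:hi, tot, TRUE),
    setting = setting, uti_related = uti
  )
}

.exclusion_reasons <- function() {
  c("male", "underage", "no_oral_rx", "no_culture_panel", "pregnancy",
    "hiv", "prior_antibiotic", "catheter", "cuti_symptom", "iv_initial",
    "complicating_comorbidity", "missing_data")
}

#' Plant patients that each fail exactly one eligibility filter
#'
#' Appends, per requested reason, patients engineered to pass every filter
#' upstream of that reason and fail it, and records the planted reason in
#' the ground truth so the attrition waterfall can be checked count-exact.
#'
#' @param tables a `synthetic_ehr` bundle from [generate_population()]
#' @param counts named integer vector, reason -> number of planted
#'   patients; names must come from the reason set (see Details); missing
#'   reasons default to 0
#' @return the bundle with planted rows appended
#' @details Reasons: `male`, `underage`, `no_oral_rx`, `no_culture_panel`
#'   (inclusion failures); `pregnancy`, `hiv`, `prior_antibiotic`,
#'   `catheter`, `cuti_symptom`, `iv_initial`, `complicating_comorbidity`,
#'   `missing_data` (exclusion failures).
#' @export
inject_exclusion_cases <- function(tables, counts) {
  stopifnot(inherits(tables, "synthetic_ehr"))
  reasons <- .exclusion_reasons()
  bad <- setdiff(names(counts), reasons)
  if (length(bad)) {
    stop_uticost("unknown exclusion reasons: ", paste(bad, collapse = ", "))
  }
  counts <- counts[counts > 0]
  if (!length(counts)) return(tables)
  if (any(counts %% 1 != 0) || any(counts < 0)) {
    stop_uticost("exclusion counts must be nonnegative integers")
  }
  if (sum(counts) > tables$config$n_patients) {
    stop_uticost("requested exclusion count exceeds n_patients")
  }
  idx0 <- as.Date("2018-06-01")
  cl <- default_code_lists()
  abx <- .panel_antibiotics()

  pat <- list(); dx <- list(); rx <- list(); cx <- list(); gt <- list()
  for (r in names(counts)) {
    k <- counts[[r]]
    id <- sprintf("X_%s_%03d", r, seq_len(k))
    pat[[r]] <- data.table(
      patient_id = id,
      sex = if (r == "male") "male" else "female",
      birth_date = idx0 - round((if (r == "underage") 11 else 30) * 365.25),
      race = "white", ethnicity = "non_hispanic", insurance = "private",
      data_end_date = as.Date("2020-03-31"),
      followup_complete = r != "missing_data"
    )
    ## index uUTI diagnosis for everyone (basis = both except no_culture_panel)
    dxr <- data.table(patient_id = id, date = idx0, code = cl$uti_codes[[1L]],
                      fever_ge_38_3 = FALSE, nausea = FALSE, vomiting = FALSE,
                      flank_pain = FALSE,
                      pregnancy_flag = r == "pregnancy", catheter_flag = FALSE)
    extra <- switch(r,
      hiv = data.table(patient_id = id, date = idx0 - 100L,
                       code = cl$hiv_codes[[1L]]),
      complicating_comorbidity = data.table(patient_id = id,
                                            date = idx0 - 50L,
                                            code = cl$complicating_codes[[1L]]),
      catheter = data.table(patient_id = id, date = idx0 + 1L,
                            code = "Z46.6", catheter_flag = TRUE),
      cuti_symptom = data.table(patient_id = id, date = idx0 + 1L,
                                code = "R50.9", fever_ge_38_3 = TRUE),
      NULL)
    if (!is.null(extra)) {
      extra <- cbind(extra,
                     data.table(fever_ge_38_3 = FALSE, nausea = FALSE,
                                vomiting = FALSE, flank_pain = FALSE,
                                pregnancy_flag = FALSE, catheter_flag = FALSE
                     )[, setdiff(names(dxr), names(extra)), with = FALSE])
      setcolorder(extra, names(dxr))
      dxr <- rbind(dxr, extra)
    }
    dx[[r]] <- dxr
    if (r != "no_oral_rx") {
      rxr <- data.table(patient_id = id, order_date = idx0,
                        drug = "nitrofurantoin", route = "oral",
                        duration_days = 5L)
      if (r == "prior_antibiotic") {
        rxr <- rbind(rxr, data.table(patient_id = id, order_date = idx0 - 30L,
                                     drug = "cephalexin", route = "oral",
                                     duration_days = 7L))
      }
      if (r == "iv_initial") {
        rxr <- rbind(rxr, data.table(patient_id = id, order_date = idx0 - 2L,
                                     drug = "ceftriaxone", route = "iv",
                                     duration_days = 3L))
      }
      rx[[r]] <- rxr
    }
    if (r != "no_culture_panel") {
      cx[[r]] <- data.table(
        patient_id = rep(id, each = length(abx)),
        culture_id = rep(sprintf("C-%s", id), each = length(abx)),
        collection_date = idx0, organism = "E. coli", cfu_per_ml = 1e5,
        antibiotic = rep(abx, times = k), result = "S"
      )
    }
    gt[[r]] <- data.table(
      patient_id = id, index_date = idx0, true_ns = 0L, true_inapp_sub = 0L,
      true_group = NA_character_, expected_cost_allcause = NA_real_,
      expected_cost_uti = NA_real_, cuti_event = 0L, planted_reason = r
    )
  }
  tables$patients <- rbind(tables$patients, rbindlist(pat))
  tables$diagnoses <- rbind(tables$diagnoses, rbindlist(dx), fill = TRUE)
  tables$prescriptions <- rbind(tables$prescriptions, rbindlist(rx))
  tables$cultures <- rbind(tables$cultures, rbindlist(cx))
  tables$ground_truth <- rbind(tables$ground_truth, rbindlist(gt))
  tables
}

#' Write / read a synthetic EHR bundle as delimited text
#'
#' Tables go to `<dir>/<name>.tsv` (UTF-8, header row, ISO-8601 dates);
#' the simulation config is stored as a JSON sidecar.
#'
#' @param tables a `synthetic_ehr` bundle
#' @param dir output directory, created if absent
#' @return `dir`, invisibly (write) / a `synthetic_ehr` bundle (read)
#' @export
write_ehr_tables <- function(tables, dir) {
  stopifnot(inherits(tables, "synthetic_ehr"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  for (nm in c("patients", "diagnoses", "encounters", "prescriptions",
               "cultures", "allergies", "ground_truth")) {
    fwrite(tables[[nm]], file.path(dir, paste0(nm, ".tsv")), sep = "\t")
  }
  jsonlite::write_json(config_as_list(tables$config),
                       file.path(dir, "sim_config.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname write_ehr_tables
#' @export
read_ehr_tables <- function(dir) {
  out <- list()
  for (nm in c("patients", "diagnoses", "encounters", "prescriptions",
               "cultures", "allergies", "ground_truth")) {
    f <- file.path(dir, paste0(nm, ".tsv"))
    if (!file.exists(f)) stop_uticost("missing table file: ", f)
    out[[nm]] <- fread(f, sep = "\t")
  }
  date_cols <- list(patients = c("birth_date", "data_end_date"),
                    diagnoses = "date", encounters = "date",
                    prescriptions = "order_date",
                    cultures = "collection_date", allergies = "record_date",
                    ground_truth = "index_date")
  for (nm in names(date_cols)) {
    for (cc in intersect(date_cols[[nm]], names(out[[nm]]))) {
      set(out[[nm]], j = cc, value = as.Date(out[[nm]][[cc]]))
    }
  }
  cfgf <- file.path(dir, "sim_config.json")
  if (file.exists(cfgf)) {
    raw <- jsonlite::read_json(cfgf, simplifyVector = TRUE)
    raw <- lapply(raw, function(x) if (is.list(x)) unlist(x) else x)
    out$config <- do.call(sim_config, raw)
  }
  structure(out, class = "synthetic_ehr")
}

## named vectors serialize to JSON objects (not nameless arrays)
config_as_list <- function(config) {
  lapply(unclass(config), function(x) {
    if (!is.null(names(x))) as.list(x) else x
  })
}
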