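## Configuration objects: formulary, code lists, Charlson weights,
## fee schedule, currency index, and the synthetic-EHR SimConfig.
## Everything the source data do not pin down is a documented default here,
## overridable by the caller; nothing downstream hard-codes a clinical list.

#' Default uUTI antibiotic formulary
#'
#' Maps each antibiotic to its therapy line and, for first-line agents, the
#' guideline-recommended course duration: nitrofurantoin 5 days, fosfomycin
#' 1 day, trimethoprim-sulfamethoxazole (SXT) 3 days. Second/third-line
#' agents carry no recommended duration (the appropriateness rule checks
#' duration for first-line monotherapy only).
#'
#' @return `data.table` with columns `drug`, `line`
#'   (`first`/`second`/`third`/`other`), `recommended_duration_days`,
#'   `class`, `route_default`.
#' @export
default_formulary <- function() {
  data.table(
    drug = c("nitrofurantoin", "sxt", "fosfomycin",
             "ciprofloxacin", "levofloxacin", "ofloxacin",
             "cephalexin", "cefaclor", "cefdinir", "cefpodoxime",
             "amoxicillin", "amoxicillin_clavulanate",
             "ceftriaxone", "gentamicin"),
    line = c("first", "first", "first",
             "second", "second", "second",
             "second", "second", "second", "second",
             "third", "third",
             "other", "other"),
    recommended_duration_days = c(5L, 3L, 1L, rep(NA_integer_, 11)),
    class = c("nitrofuran", "folate_inhibitor", "phosphonic",
              "fluoroquinolone", "fluoroquinolone", "fluoroquinolone",
              "cephalosporin", "cephalosporin", "cephalosporin",
              "cephalosporin", "beta_lactam", "beta_lactam",
              "cephalosporin", "aminoglycoside"),
    route_default = c(rep("oral", 12), "iv", "iv")
  )
}

#' uUTI-indicated antibiotic set
#'
#' The antibiotics counted when aggregating isolate susceptibility to a
#' person-level status: all first-, second- and third-line formulary agents
#' (IV-only `other` agents are not uUTI-indicated).
#'
#' @param formulary a formulary table, see [default_formulary()]
#' @return character vector of drug ids
#' @export
indicated_antibiotics <- function(formulary = default_formulary()) {
  formulary[line %in% c("first", "second", "third"), drug]
}

#' Default diagnosis code lists
#'
#' ICD-10-style code prefixes used by the cohort filters. The real study's
#' lists are not public, so these are compact stand-ins with the right
#' semantics; all are overridable.
#'
#' @return named list of character vectors: `uti_codes` (index uUTI),
#'   `cuti_codes` (complicated-UTI progression), `hiv_codes`,
#'   `complicating_codes` (comorbidities ruling out uUTI),
#'   `infection_codes` (prior-infection sensitivity filter),
#'   `uropathogens` (organisms whose culture can define an index event).
#' @export
default_code_lists <- function() {
  list(
    uti_codes = c("N39.0", "N30.0"),
    cuti_codes = c("N10", "N39.9C"),
    hiv_codes = c("B20", "B21", "B22", "B24"),
    complicating_codes = c("C80", "D70", "D84", "E11.62", "O09"),
    infection_codes = c("A49", "J06", "L03", "J18"),
    uropathogens = c("E. coli", "K. pneumoniae", "P. mirabilis",
                     "E. faecalis", "S. saprophyticus")
  )
}

#' Charlson comorbidity weights and code map
#'
#' Classic Charlson weights for the comorbidity categories tracked in the
#' baseline characteristics table, with an ICD-10-style prefix map used to
#' assign diagnosis codes to categories.
#'
#' @return list with `weights` (named integer vector, category -> weight)
#'   and `code_map` (`data.table` of `prefix`, `category`).
#' @export
default_charlson <- function() {
  weights <- c(
    myocardial_infarction = 1L, congestive_heart_failure = 1L,
    peripheral_vascular_disease = 1L, cerebrovascular_disease = 1L,
    dementia = 1L, chronic_pulmonary_disease = 1L, rheumatic_disease = 1L,
    peptic_ulcer_disease = 1L, mild_liver_disease = 1L,
    hemiparesis = 2L, renal_disease = 2L,
    moderate_severe_liver_disease = 3L
  )
  code_map <- data.table(
    prefix = c("I21", "I50", "I73", "I63", "F03", "J44", "M05",
               "K25", "K73", "G81", "N18", "K72"),
    category = names(weights)
  )
  list(weights = weights, code_map = code_map)
}

#' Default fee schedule
#'
#' Unit costs per encounter setting and per drug-day, standing in for
#' Medicare fee-for-service rates and wholesale acquisition costs. Values
#' are plausible 2020 USD magnitudes; they are configuration, not claims.
#'
#' @return list with `setting_cost` (named numeric), `drug_cost_per_day`
#'   (named numeric, covers the default formulary) and `currency_year`.
#' @export
default_fee_schedule <- function() {
  list(
    setting_cost = c(
      inpatient = 15000, emergency = 1200, outpatient_clinic = 150,
      outpatient_ambulatory_surgery = 2000, outpatient_other = 120
    ),
    drug_cost_per_day = c(
      nitrofurantoin = 2, sxt = 1, fosfomycin = 50,
      ciprofloxacin = 1, levofloxacin = 2, ofloxacin = 3,
      cephalexin = 1, cefaclor = 4, cefdinir = 5, cefpodoxime = 6,
      amoxicillin = 1, amoxicillin_clavulanate = 3,
      ceftriaxone = 30, gentamicin = 25
    ),
    currency_year = 2020L
  )
}

#' Default medical-care price index
#'
#' Year -> index level used by [adjust_currency()] to restate costs in
#' 2020 dollars. Levels approximate the US medical-care CPI trajectory.
#'
#' @return named numeric vector, names are years
#' @export
default_price_index <- function() {
  c(`2016` = 471.3, `2017` = 483.4, `2018` = 492.5,
    `2019` = 505.4, `2020` = 518.9)
}

#' Synthetic EHR simulation configuration
#'
#' Bundles and validates every knob of the generator. Defaults state the
#' world the pipeline is tested against: a cohort like the one analysed —
#' 40.2% of patients not-susceptible to at least one uUTI-indicated
#' antibiotic, inappropriate-or-suboptimal prescribing in 48.2% of
#' not-susceptible versus 23.5% of susceptible patients, 5.2% allergy
#' prevalence, mean age 43.5 years, and follow-up costs whose group means
#' follow the reference cost times a per-exposure-group multiplier.
#'
#' @param n_patients number of core (non-planted) patients
#' @param seed integer RNG seed; identical configs and seeds give
#'   byte-identical tables
#' @param prevalence_not_susceptible marginal probability that a patient is
#'   not-susceptible at person level
#' @param p_inappropriate_given_ns,p_inappropriate_given_s probability of
#'   inappropriate-or-suboptimal prescribing given susceptibility status
#' @param allergy_prevalence probability of a recorded uUTI-antibiotic
#'   allergy
#' @param age_mean,age_sd age distribution (normal truncated at 12 years)
#' @param race_probs,insurance_probs named probability maps (sum to 1)
#' @param ethnicity_probs named probability map
#' @param comorbidity_probs named per-category probabilities of a baseline
#'   Charlson comorbidity (need not sum to 1; independent Bernoulli)
#' @param confounding named coefficients (`age`, `white`, `private`) of the
#'   logistic index tilting not-susceptibility, so matching has real work
#'   to do; the intercept is solved so the marginal prevalence is honoured
#' @param cost_shape gamma shape of follow-up costs
#' @param base_cost_allcause,base_cost_uti mean follow-up costs (USD) in
#'   the reference group (susceptible + appropriate)
#' @param group_cost_multipliers named positive multipliers per exposure
#'   group (`S_app`, `S_inapp_sub`, `NS_app`, `NS_inapp_sub`)
#' @param p_cuti_s,p_cuti_ns probability of progression to complicated UTI
#'   in follow-up by susceptibility status
#' @param followup_days,baseline_days observation windows in days
#' @param basis_probs named probabilities that the index event is
#'   identifiable by `both`, `diagnosis_code` only, or `culture` only
#' @return validated list of class `sim_config`
#' @export
sim_config <- function(n_patients = 2565L,
                       seed = 1L,
                       prevalence_not_susceptible = 0.402,
                       p_inappropriate_given_ns = 0.482,
                       p_inappropriate_given_s = 0.235,
                       allergy_prevalence = 0.052,
                       age_mean = 43.5, age_sd = 18,
                       race_probs = c(white = 0.595, african_american = 0.255,
                                      asian = 0.033, other = 0.059,
                                      unknown = 0.058),
                       ethnicity_probs = c(non_hispanic = 0.872,
                                           hispanic = 0.030, other = 0.004,
                                           unknown = 0.094),
                       insurance_probs = c(private = 0.613,
                                           medicare_medicaid = 0.157,
                                           other = 0.230),
                       comorbidity_probs = c(chronic_pulmonary_disease = 0.022,
                                             dementia = 0.007,
                                             rheumatic_disease = 0.006,
                                             cerebrovascular_disease = 0.004,
                                             congestive_heart_failure = 0.002,
                                             mild_liver_disease = 0.003,
                                             peripheral_vascular_disease = 0.003,
                                             peptic_ulcer_disease = 0.001,
                                             renal_disease = 0.001),
                       confounding = c(age = 0.015, white = -0.12,
                                       private = -0.20),
                       cost_shape = 1.5,
                       base_cost_allcause = 2532,
                       base_cost_uti = 945,
                       group_cost_multipliers = c(S_app = 1.000,
                                                  S_inapp_sub = 1.105,
                                                  NS_app = 1.261,
                                                  NS_inapp_sub = 1.352),
                       p_cuti_s = 0.04, p_cuti_ns = 0.10,
                       followup_days = 180L, baseline_days = 180L,
                       basis_probs = c(both = 0.60, diagnosis_code = 0.20,
                                       culture = 0.20)) {
  if (length(n_patients) != 1 || is.na(n_patients) || n_patients < 1) {
    stop_uticost("n_patients must be a positive integer")
  }
  check_prob(prevalence_not_susceptible, "prevalence_not_susceptible")
  check_prob(p_inappropriate_given_ns, "p_inappropriate_given_ns")
  check_prob(p_inappropriate_given_s, "p_inappropriate_given_s")
  check_prob(allergy_prevalence, "allergy_prevalence")
  check_prob(p_cuti_s, "p_cuti_s")
  check_prob(p_cuti_ns, "p_cuti_ns")
  check_prob_map(race_probs, "race_probs")
  check_prob_map(ethnicity_probs, "ethnicity_probs")
  check_prob_map(insurance_probs, "insurance_probs")
  check_prob_map(basis_probs, "basis_probs")
  if (any(comorbidity_probs < 0 | comorbidity_probs > 1)) {
    stop_uticost("comorbidity_probs must lie in [0, 1]")
  }
  if (cost_shape <= 0) stop_uticost("cost_shape must be positive")
  if (base_cost_uti > base_cost_allcause) {
    stop_uticost("base_cost_uti cannot exceed base_cost_allcause")
  }
  need <- c("S_app", "S_inapp_sub", "NS_app", "NS_inapp_sub")
  if (!all(need %in% names(group_cost_multipliers)) ||
      any(group_cost_multipliers <= 0)) {
    stop_uticost("group_cost_multipliers must be positive and cover ",
                 paste(need, collapse = ", "))
  }
  if (age_sd <= 0) stop_uticost("age_sd must be positive")
  if (followup_days < 1 || baseline_days < 1) {
    stop_uticost("followup_days and baseline_days must be >= 1")
  }
  structure(list(
    n_patients = as.integer(n_patients), seed = as.integer(seed),
    prevalence_not_susceptible = prevalence_not_susceptible,
    p_inappropriate_given_ns = p_inappropriate_given_ns,
    p_inappropriate_given_s = p_inappropriate_given_s,
    allergy_prevalence = allergy_prevalence,
    age_mean = age_mean, age_sd = age_sd,
    race_probs = race_probs, ethnicity_probs = ethnicity_probs,
    insurance_probs = insurance_probs,
    comorbidity_probs = comorbidity_probs,
    confounding = confounding,
    cost_shape = cost_shape,
    base_cost_allcause = base_cost_allcause,
    base_cost_uti = base_cost_uti,
    group_cost_multipliers = group_cost_multipliers[need],
    p_cuti_s = p_cuti_s, p_cuti_ns = p_cuti_ns,
    followup_days = as.integer(followup_days),
    baseline_days = as.integer(baseline_days),
    basis_probs = basis_probs[c("both", "diagnosis_code", "culture")]
  ), class = "sim_config")
}

#' Exposure group levels
#'
#' The four-level exposure: susceptibility status crossed with final
#' treatment adjudication. `S_app` (susceptible + appropriate) is the
#' reference.
#' @return character vector of the four levels, reference first
#' @export
exposure_levels <- function() c("S_app", "S_inapp_sub", "NS_app", "NS_inapp_sub")
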