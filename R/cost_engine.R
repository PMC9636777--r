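## HCRU tabulation and cost construction. All windows are half-open
## [start, end) in whole calendar days relative to each patient's index
## date, so an event on the index date belongs to follow-up, not baseline.

.settings <- function() {
  c("inpatient", "emergency", "outpatient_clinic",
    "outpatient_ambulatory_surgery", "outpatient_other")
}

#' Tabulate healthcare resource use in a window
#'
#' Counts encounters by setting, drug orders, and an any-antibiotic
#' indicator for each patient, over the per-patient window
#' `[index + offset_start, index + offset_end)`.
#'
#' @param encounters,prescriptions EHR tables
#' @param index_dates `data.table` of `patient_id`, `index_date`
#' @param offset_start,offset_end window offsets in days (half-open);
#'   baseline is `(-180, 0)`, follow-up `(0, followup_days)`
#' @return `data.table`, one row per patient in `index_dates`: counts per
#'   setting, `drug_orders`, `any_antibiotic`
#' @export
tabulate_hcru <- function(encounters, prescriptions, index_dates,
                          offset_start, offset_end) {
  assert_cols(encounters, c("patient_id", "date", "setting"))
  if (offset_end <= offset_start) stop_uticost("window must be non-empty")
  enc <- encounters[index_dates, on = .(patient_id), nomatch = NULL,
                    allow.cartesian = TRUE]
  enc <- enc[date >= index_date + offset_start &
               date < index_date + offset_end]
  cnt <- dcast(enc, patient_id ~ setting, fun.aggregate = length,
               value.var = "date")
  for (s in setdiff(.settings(), names(cnt))) cnt[, (s) := 0L]
  rx <- prescriptions[index_dates, on = .(patient_id), nomatch = NULL,
                      allow.cartesian = TRUE]
  rx <- rx[order_date >= index_date + offset_start &
             order_date < index_date + offset_end]
  rxc <- rx[, .(drug_orders = .N, any_antibiotic = 1L), by = patient_id]
  out <- Reduce(function(a, b) merge(a, b, by = "patient_id", all.x = TRUE),
                list(index_dates[, .(patient_id)], cnt, rxc))
  num <- setdiff(names(out), "patient_id")
  for (cc in num) set(out, which(is.na(out[[cc]])), cc, 0L)
  setcolorder(out, c("patient_id", .settings(), "drug_orders",
                     "any_antibiotic"))
  setorder(out, patient_id)
  out[]
}

#' Compute all-cause and UTI-related costs
#'
#' All-cause cost is encounter counts times setting unit costs plus drug
#' days times per-day prices, over the follow-up window. The UTI-related
#' subset keeps encounters flagged UTI-related and drug orders of
#' uUTI-indicated antibiotics within the episode window
#' `[index - 5, index + episode_days]`.
#'
#' @inheritParams tabulate_hcru
#' @param fee_schedule see [default_fee_schedule()]
#' @param indicated_set uUTI-indicated antibiotics (drug attribution rule)
#' @param episode_days length of the UTI episode for drug attribution
#'   (default 28)
#' @return `data.table` of `patient_id`, `all_cause_cost`,
#'   `uti_related_cost`
#' @export
compute_costs <- function(encounters, prescriptions, index_dates,
                          fee_schedule = default_fee_schedule(),
                          offset_start = 0L, offset_end = 180L,
                          indicated_set = indicated_antibiotics(),
                          episode_days = 28L) {
  enc <- encounters[index_dates, on = .(patient_id), nomatch = NULL,
                    allow.cartesian = TRUE]
  enc <- enc[date >= index_date + offset_start &
               date < index_date + offset_end]
  unpriced <- setdiff(unique(enc$setting), names(fee_schedule$setting_cost))
  if (length(unpriced)) {
    stop_uticost("unpriced encounter settings: ",
                 paste(unpriced, collapse = ", "))
  }
  enc[, value := fee_schedule$setting_cost[setting]]
  ec <- enc[, .(enc_all = sum(value),
                enc_uti = sum(value[uti_related == TRUE])), by = patient_id]

  rx <- prescriptions[index_dates, on = .(patient_id), nomatch = NULL,
                      allow.cartesian = TRUE]
  rx <- rx[order_date >= index_date + offset_start &
             order_date < index_date + offset_end]
  unpriced <- setdiff(unique(rx$drug), names(fee_schedule$drug_cost_per_day))
  if (length(unpriced)) {
    stop_uticost("unpriced drugs: ", paste(unpriced, collapse = ", "))
  }
  rx[, value := fee_schedule$drug_cost_per_day[drug] * duration_days]
  rx[, uti_related := drug %chin% indicated_set &
       order_date >= index_date - 5L &
       order_date <= index_date + episode_days]
  rc <- rx[, .(rx_all = sum(value), rx_uti = sum(value[uti_related])),
           by = patient_id]

  out <- Reduce(function(a, b) merge(a, b, by = "patient_id", all.x = TRUE),
                list(index_dates[, .(patient_id)], ec, rc))
  for (cc in c("enc_all", "enc_uti", "rx_all", "rx_uti")) {
    set(out, which(is.na(out[[cc]])), cc, 0)
  }
  out[, `:=`(all_cause_cost = enc_all + rx_all,
             uti_related_cost = enc_uti + rx_uti)]
  out[, c("enc_all", "enc_uti", "rx_all", "rx_uti") := NULL]
  setorder(out, patient_id)
  out[]
}

#' Winsorize costs at a percentile
#'
#' Values above the threshold (linear-interpolation percentile, base R
#' type 7) are capped at it; values at or below are unchanged.
#'
#' @param x numeric cost vector (non-empty)
#' @param percentile cap percentile in (0, 100]; default 98
#' @return winsorized vector, same length and order as `x`
#' @export
winsorize <- function(x, percentile = 98) {
  if (!length(x)) stop_uticost("winsorize: empty input")
  cap <- unname(quantile(x, percentile / 100, type = 7, names = FALSE))
  pmin(x, cap)
}

#' Adjust costs to a target currency year
#'
#' Multiplies by the ratio of price-index levels:
#' `cost * index[target] / index[source]`.
#'
#' @param cost numeric cost vector
#' @param source_year year the costs are denominated in
#' @param index_table named numeric vector of index levels by year, see
#'   [default_price_index()]
#' @param target_year defaults to 2020
#' @return adjusted costs
#' @export
adjust_currency <- function(cost, source_year,
                            index_table = default_price_index(),
                            target_year = 2020) {
  sy <- as.character(source_year)
  ty <- as.character(target_year)
  if (!sy %in% names(index_table) || !ty %in% names(index_table)) {
    stop_uticost("price index table does not cover years ", sy, " and ", ty)
  }
  cost * unname(index_table[ty] / index_table[sy])
}
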