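## End-to-end orchestration: generate -> cohort -> classify -> cost ->
## analyze -> sensitivity -> report. Every intermediate table is persisted
## as delimited text so each stage is independently re-runnable, and a
## manifest records config, seed and package version.

#' Allergy tabulation by susceptibility arm
#'
#' Per-antibiotic allergy proportions among cohort patients, by
#' susceptibility arm, with the arm difference, a binary-covariate
#' standardized mean difference and, for each row, the split of allergic
#' patients across arms. Rows cover any uUTI antibiotic, any first-,
#' second- and third-line agent, and each indicated drug.
#'
#' @param allergies allergy table
#' @param susceptibility `data.table` of `patient_id`, `person_level`
#'   covering the cohort
#' @param formulary see [default_formulary()]
#' @return `data.table`: `variable`, `pct_susceptible`, `n_susceptible`,
#'   `pct_not_susceptible`, `n_not_susceptible`, `diff`, `smd`,
#'   `pct_overall`, `n_overall`, `share_susceptible`,
#'   `share_not_susceptible`
#' @export
allergy_tabulation <- function(allergies, susceptibility,
                               formulary = default_formulary()) {
  assert_cols(susceptibility, c("patient_id", "person_level"))
  ns_ids <- susceptibility[person_level == "not_susceptible", patient_id]
  s_ids <- susceptibility[person_level == "susceptible", patient_id]
  n_s <- length(s_ids)
  n_ns <- length(ns_ids)
  if (n_s + n_ns == 0) stop_uticost("empty cohort")
  alg <- allergies[patient_id %chin% susceptibility$patient_id]
  lines_of <- function(ln) formulary[line %chin% ln, drug]
  drug_sets <- c(
    list(any_uti_antibiotic = lines_of(c("first", "second", "third")),
         any_first_line = lines_of("first"),
         any_second_line = lines_of("second"),
         any_third_line = lines_of("third")),
    setNames(as.list(lines_of(c("first", "second", "third"))),
             lines_of(c("first", "second", "third")))
  )
  row <- function(v, drugs) {
    who <- unique(alg[drug %chin% drugs, patient_id])
    ks <- sum(s_ids %chin% who)
    kns <- sum(ns_ids %chin% who)
    p1 <- ks / n_s
    p2 <- kns / n_ns
    den <- sqrt((p1 * (1 - p1) + p2 * (1 - p2)) / 2)
    data.table(
      variable = v,
      pct_susceptible = pct(ks, n_s, 2), n_susceptible = ks,
      pct_not_susceptible = pct(kns, n_ns, 2), n_not_susceptible = kns,
      diff = pct(kns, n_ns, 2) - pct(ks, n_s, 2),
      smd = if (den == 0) 0 else abs(p2 - p1) / den,
      pct_overall = pct(ks + kns, n_s + n_ns), n_overall = ks + kns,
      share_susceptible = if (ks + kns > 0) pct(ks, ks + kns) else NA_real_,
      share_not_susceptible = if (ks + kns > 0) pct(kns, ks + kns)
        else NA_real_
    )
  }
  rbindlist(Map(row, names(drug_sets), drug_sets))
}

#' Run the full pipeline and write all reports
#'
#' Generates (or ingests) the EHR tables, builds the cohort, adjudicates
#' treatments, constructs costs, fits the matched analyses and the
#' sensitivity battery, and writes the report set: attrition waterfall,
#' classification summary, allergy tabulation, pre/post-match balance
#' table, stratified four-group cost table, sensitivity table, plus a
#' manifest with config, seed and versions. Two runs with the same config
#' and seed produce byte-identical reports.
#'
#' @param config a [sim_config()]; its seed is overridden by `seed` when
#'   given
#' @param out_dir output directory
#' @param seed optional integer overriding `config$seed`
#' @param tables optional pre-built EHR bundle (skips generation)
#' @param planted_exclusions named counts for [inject_exclusion_cases()]
#'   (ignored when `tables` is supplied)
#' @param scenarios sensitivity scenario names
#' @param fee_schedule,code_lists,formulary configuration
#' @return invisible list of all computed artifacts
#' @export
run_pipeline <- function(config = sim_config(), out_dir, seed = NULL,
                         tables = NULL,
                         planted_exclusions = c(pregnancy = 5L,
                                                cuti_symptom = 5L,
                                                catheter = 5L,
                                                iv_initial = 5L),
                         scenarios = c("baseline", "strict", "loose", "fu30",
                                       "fu360", "no_prior_infection",
                                       "fq_only"),
                         fee_schedule = default_fee_schedule(),
                         code_lists = default_code_lists(),
                         formulary = default_formulary()) {
  if (!is.null(seed)) config$seed <- as.integer(seed)
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  t0 <- Sys.time()
  log_stage <- function(stage, n) {
    message(sprintf("[%s] %-22s rows=%d (%.1fs)",
                    format(Sys.time(), "%H:%M:%S"), stage, n,
                    as.numeric(difftime(Sys.time(), t0, units = "secs"))))
  }
  if (is.null(tables)) {
    tables <- generate_population(config, fee_schedule)
    if (length(planted_exclusions)) {
      tables <- inject_exclusion_cases(tables, planted_exclusions)
    }
  }
  write_ehr_tables(tables, file.path(out_dir, "tables"))
  log_stage("generate", nrow(tables$patients))

  asm <- assemble_analysis(tables, "baseline", code_lists, formulary,
                           fee_schedule)
  dat <- asm$data
  fwrite(asm$attrition, file.path(out_dir, "attrition.tsv"), sep = "\t")
  fwrite(dat, file.path(out_dir, "analysis_dataset.tsv"), sep = "\t")
  log_stage("cohort+classify", nrow(dat))

  cs <- classification_summary(asm$labels)
  fwrite(cs, file.path(out_dir, "classification_summary.tsv"), sep = "\t")

  at <- allergy_tabulation(tables$allergies,
                           dat[, .(patient_id, person_level)], formulary)
  fwrite(at, file.path(out_dir, "allergy_table.tsv"), sep = "\t")

  ps <- estimate_propensity(dat, "ns", ps_covariates("susceptibility"))
  mc <- match_1to1(ps$scores, dat$ns == 1, ids = dat$patient_id,
                   seed = config$seed)
  bt <- balance_table(dat, ps_covariates("susceptibility"), "ns", mc)
  fwrite(bt, file.path(out_dir, "balance_table.tsv"), sep = "\t")
  log_stage("match+balance", nrow(mc$pairs))

  sc <- stratified_cost_report(dat)
  fwrite(sc, file.path(out_dir, "stratified_costs.tsv"), sep = "\t")

  sens <- run_sensitivity(tables, seed = config$seed, scenarios = scenarios,
                          code_lists = code_lists, formulary = formulary,
                          fee_schedule = fee_schedule)
  fwrite(sens, file.path(out_dir, "sensitivity.tsv"), sep = "\t")
  log_stage("sensitivity", nrow(sens))

  cfg_plain <- config_as_list(config)
  manifest <- list(
    package = "uticost",
    version = as.character(utils::packageVersion("uticost")),
    seed = config$seed,
    config = cfg_plain,
    config_hash = .config_hash(cfg_plain),
    n_patients_generated = nrow(tables$patients),
    n_cohort = nrow(dat),
    n_matched_pairs = nrow(mc$pairs),
    scenarios = scenarios
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(tables = tables, analysis = asm, classification = cs,
                 allergy = at, balance = bt, matched = mc,
                 stratified = sc, sensitivity = sens, manifest = manifest))
}

## order-stable hash of the config without external digest dependencies
## (polynomial rolling hash over the serialized bytes, kept in double range)
.config_hash <- function(cfg) {
  s <- jsonlite::toJSON(cfg[order(names(cfg))], auto_unbox = TRUE,
                        digits = NA)
  h <- 5381
  for (b in as.integer(charToRaw(as.character(s)))) {
    h <- (h * 33 + b) %% 2147483647
  }
  sprintf("%08x", as.integer(h))
}

#' Command-line entry point
#'
#' Thin wrapper so the pipeline can run as
#' `Rscript -e 'uticost::uticost_cli()' -- --seed 7 --out runs/demo`.
#' Flags: `--seed`, `--out`, `--n` (patients), `--scenario`
#' (comma-separated list or `all`).
#'
#' @param args character vector of arguments (default: command line)
#' @return invisibly, the [run_pipeline()] artifact list
#' @export
uticost_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  val <- function(flag, default) {
    i <- which(args == flag)
    if (length(i) && i < length(args)) args[i + 1] else default
  }
  seed <- as.integer(val("--seed", "1"))
  out <- val("--out", "uticost_run")
  n <- as.integer(val("--n", "2565"))
  sc <- val("--scenario", "all")
  scenarios <- if (identical(sc, "all")) {
    c("baseline", "strict", "loose", "fu30", "fu360",
      "no_prior_infection", "fq_only")
  } else {
    strsplit(sc, ",", fixed = TRUE)[[1]]
  }
  run_pipeline(sim_config(n_patients = n, seed = seed), out_dir = out,
               scenarios = scenarios)
}
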