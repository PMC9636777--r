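## Propensity-score estimation, 1:1 greedy nearest-neighbour matching on
## the logit scale, covariate balance diagnostics, and adjusted gamma
## log-link cost models with recycled-prediction dollar differences.

#' Default propensity-score covariates
#'
#' The susceptibility contrast uses age, White race, private insurance,
#' baseline inpatient visits and baseline outpatient clinic-or-other
#' visits; the appropriateness contrast uses the demographic trio (the
#' utilization covariates are switchable on).
#'
#' @param contrast `"susceptibility"` or `"appropriateness"`
#' @return character vector of covariate column names
#' @export
ps_covariates <- function(contrast = c("susceptibility", "appropriateness")) {
  contrast <- match.arg(contrast)
  base <- c("age_at_index", "white", "private_insurance")
  if (contrast == "susceptibility") {
    c(base, "base_inpatient", "base_outpatient")
  } else {
    base
  }
}

#' Estimate a propensity-score model
#'
#' Logistic regression of group membership on the covariates. Perfect or
#' near-perfect separation is reported with a warning rather than silently
#' absorbed.
#'
#' @param data analysis table, one row per patient
#' @param treatment name of a logical/0-1 column marking the treated group
#' @param covariates covariate column names, see [ps_covariates()]
#' @return list of class `ps_model`: `model`, `scores` (in (0,1)),
#'   `covariates`, `treatment`
#' @export
estimate_propensity <- function(data, treatment,
                                covariates = ps_covariates()) {
  assert_cols(data, c(treatment, covariates))
  f <- as.formula(paste(treatment, "~", paste(covariates, collapse = " + ")))
  fit <- suppressWarnings(glm(f, family = binomial(), data = data))
  scores <- fitted(fit)
  eps <- 1e-8
  if (any(scores < eps | scores > 1 - eps)) {
    warning("propensity model shows (near-)perfect separation for some ",
            "patients", call. = FALSE)
  }
  scores <- pmin(pmax(scores, eps), 1 - eps)
  structure(list(model = fit, scores = unname(scores),
                 covariates = covariates, treatment = treatment),
            class = "ps_model")
}

#' 1:1 greedy nearest-neighbour matching without replacement
#'
#' Treated patients are processed in seed-randomized order; each takes the
#' nearest still-available control on the logit propensity scale, provided
#' the distance is within the caliper. Ties go to the earlier control in
#' the data. Deterministic given the seed.
#'
#' @param scores propensity scores in (0,1)
#' @param treated logical vector, same length
#' @param ids patient ids (default positional)
#' @param caliper maximum logit-scale distance; default 0.2 standard
#'   deviations of the logit scores (`NULL` for no caliper)
#' @param seed integer seed for the processing order
#' @return list of class `matched_cohort`: `pairs` (`data.table` of
#'   `treated_id`, `control_id`, `distance`), `caliper`, `unmatched`
#' @export
match_1to1 <- function(scores, treated, ids = NULL, caliper = NULL,
                       seed = 1L) {
  stopifnot(length(scores) == length(treated))
  treated <- as.logical(treated)
  if (!any(treated) || all(treated)) {
    stop_uticost("both groups must be non-empty")
  }
  if (is.null(ids)) ids <- as.character(seq_along(scores))
  lg <- qlogis(pmin(pmax(scores, 1e-12), 1 - 1e-12))
  if (is.null(caliper)) caliper <- 0.2 * sd(lg)
  t_ix <- which(treated)
  c_ix <- which(!treated)
  ord <- withr::with_seed(seed, sample(seq_along(t_ix)))
  t_ix <- t_ix[ord]
  c_lg <- lg[c_ix]
  avail <- rep(TRUE, length(c_ix))
  pairs <- vector("list", length(t_ix))
  for (k in seq_along(t_ix)) {
    d <- abs(c_lg - lg[t_ix[k]])
    d[!avail] <- Inf
    j <- which.min(d)
    if (is.finite(d[j]) && d[j] <= caliper) {
      avail[j] <- FALSE
      pairs[[k]] <- data.table(treated_id = ids[t_ix[k]],
                               control_id = ids[c_ix[j]],
                               distance = d[j])
    }
  }
  pairs <- rbindlist(pairs[!vapply(pairs, is.null, logical(1))])
  if (!nrow(pairs)) {
    pairs <- data.table(treated_id = character(), control_id = character(),
                        distance = numeric())
  }
  matched <- c(pairs$treated_id, pairs$control_id)
  structure(list(pairs = pairs, caliper = caliper,
                 unmatched = setdiff(ids, matched)),
            class = "matched_cohort")
}

#' Standardized mean difference
#'
#' `|mean_a - mean_b| / sqrt((var_a + var_b) / 2)`. For binary (0/1)
#' covariates the variances are `p(1-p)`. Returns 0 when the pooled
#' variance is 0 and means are equal; `Inf` (with a warning) when it is 0
#' with unequal means.
#'
#' @param x covariate values (numeric or logical)
#' @param group two-level grouping vector
#' @return nonnegative scalar
#' @export
standardized_mean_difference <- function(x, group) {
  x <- as.numeric(x)
  g <- unique(group)
  if (length(g) != 2) stop_uticost("group must have exactly two levels")
  a <- x[group == g[1]]
  b <- x[group == g[2]]
  binary <- all(x %in% c(0, 1))
  v <- function(z) {
    if (binary) mean(z) * (1 - mean(z)) else var(z)
  }
  num <- abs(mean(a) - mean(b))
  den <- sqrt((v(a) + v(b)) / 2)
  if (den == 0) {
    if (num == 0) return(0)
    warning("SMD undefined: zero pooled variance with unequal means",
            call. = FALSE)
    return(Inf)
  }
  num / den
}

#' Pre/post-matching balance table
#'
#' Per-covariate group means and standardized mean differences before
#' matching (all rows) and after (matched rows only).
#'
#' @param data analysis table with an id column
#' @param covariates covariate column names
#' @param treatment treated-group column name
#' @param matched a `matched_cohort` from [match_1to1()]
#' @param id id column name (default `patient_id`)
#' @return `data.table`: `variable`, `mean_treated_pre`, `mean_control_pre`,
#'   `smd_pre`, `mean_treated_post`, `mean_control_post`, `smd_post`
#' @export
balance_table <- function(data, covariates, treatment, matched,
                          id = "patient_id") {
  assert_cols(data, c(id, treatment, covariates))
  post <- data[data[[id]] %in% c(matched$pairs$treated_id,
                                 matched$pairs$control_id), ]
  row <- function(v) {
    tr <- as.logical(data[[treatment]])
    trp <- as.logical(post[[treatment]])
    data.table(
      variable = v,
      mean_treated_pre = mean(as.numeric(data[[v]])[tr]),
      mean_control_pre = mean(as.numeric(data[[v]])[!tr]),
      smd_pre = standardized_mean_difference(data[[v]], tr),
      mean_treated_post = mean(as.numeric(post[[v]])[trp]),
      mean_control_post = mean(as.numeric(post[[v]])[!trp]),
      smd_post = standardized_mean_difference(post[[v]], trp)
    )
  }
  rbindlist(lapply(covariates, row))
}

#' Fit an adjusted gamma log-link cost model
#'
#' Gamma-family, log-link GLM of cost on the exposure plus adjusters.
#' Zero costs are incompatible with the gamma likelihood and are lifted to
#' a small offset (default $0.01) unless `drop_zeros`. The adjusted dollar
#' difference per exposure level is computed by recycled predictions:
#' every patient is predicted under each exposure level, predictions are
#' averaged, and the reference level's mean is subtracted. P-values come
#' from the exposure coefficients (model-based standard errors).
#'
#' @param data analysis table
#' @param outcome cost column name
#' @param exposure exposure column name (factor; first level = reference)
#' @param adjusters further covariate column names
#' @param zero_offset replacement for non-positive costs (default 0.01)
#' @param drop_zeros if `TRUE`, drop non-positive costs instead
#' @return list of class `cost_model_result`: `estimates` (`data.table` of
#'   `group`, `n`, `adjusted_mean`, `diff_vs_ref`, `p_value`), `model`,
#'   `family`, `link`, `converged`
#' @export
fit_cost_model <- function(data, outcome, exposure, adjusters = character(),
                           zero_offset = 0.01, drop_zeros = FALSE) {
  assert_cols(data, c(outcome, exposure, adjusters))
  dt <- as.data.table(data)
  y <- dt[[outcome]]
  if (drop_zeros) {
    dt <- dt[y > 0]
  } else {
    dt[[outcome]] <- ifelse(y <= 0, zero_offset, y)
  }
  if (!is.factor(dt[[exposure]])) dt[[exposure]] <- factor(dt[[exposure]])
  dt[[exposure]] <- droplevels(dt[[exposure]])
  lv <- levels(dt[[exposure]])
  rhs <- paste(c(exposure, adjusters), collapse = " + ")
  f <- as.formula(paste(outcome, "~", rhs))
  fit <- glm(f, family = Gamma(link = "log"), data = dt)
  if (!fit$converged) {
    warning("gamma GLM did not converge (", outcome, " ~ ", rhs, ")",
            call. = FALSE)
  }
  ## recycled predictions
  mu <- vapply(lv, function(l) {
    nd <- copy(dt)
    nd[[exposure]] <- factor(l, levels = lv)
    mean(predict(fit, newdata = nd, type = "response"))
  }, numeric(1))
  cf <- summary(fit)$coefficients
  pv <- setNames(rep(NA_real_, length(lv)), lv)
  for (l in lv[-1]) {
    nm <- paste0(exposure, l)
    if (nm %in% rownames(cf)) pv[l] <- cf[nm, 4]
  }
  est <- data.table(group = lv,
                    n = as.integer(table(dt[[exposure]])[lv]),
                    adjusted_mean = unname(mu),
                    diff_vs_ref = unname(mu - mu[1]),
                    p_value = unname(pv))
  structure(list(estimates = est, model = fit, family = "Gamma",
                 link = "log", converged = fit$converged),
            class = "cost_model_result")
}

.sig_marker <- function(p) {
  ifelse(is.na(p), "", ifelse(p < 0.001, "***",
                              ifelse(p < 0.01, "**",
                                     ifelse(p < 0.05, "*", ""))))
}

#' Stratified cost report over the four exposure groups
#'
#' Fits adjusted gamma log-link models for all-cause and UTI-related costs
#' against the 4-level exposure and reports, per group, the adjusted mean
#' cost, the dollar difference versus the susceptible-appropriate reference
#' and significance markers (* p<0.05, dagger p<0.01, double-dagger
#' p<0.001). Groups with no patients are reported as missing rows rather
#' than crashing.
#'
#' @param data analysis table with `exposure_group` and cost columns
#' @param adjusters covariate column names for model adjustment
#' @param outcomes named character vector mapping report labels to cost
#'   columns
#' @return `data.table`: `outcome`, `group`, `n`, `adjusted_mean`,
#'   `diff_vs_ref`, `p_value`, `sig`
#' @export
stratified_cost_report <- function(data,
                                   adjusters = c("cci", "base_inpatient",
                                                 "base_emergency",
                                                 "base_outpatient",
                                                 "base_drug_orders"),
                                   outcomes = c(all_cause = "all_cause_cost",
                                                uti_related = "uti_related_cost")) {
  dt <- as.data.table(data)
  if (!nrow(dt[exposure_group == exposure_levels()[1]])) {
    stop_uticost("reference exposure group is empty")
  }
  out <- lapply(names(outcomes), function(lbl) {
    res <- fit_cost_model(dt, outcomes[[lbl]], "exposure_group", adjusters)
    est <- copy(res$estimates)
    est[, `:=`(outcome = lbl, sig = .sig_marker(p_value))]
    ## flag configured-but-absent groups explicitly
    missing_lv <- setdiff(exposure_levels(), est$group)
    if (length(missing_lv)) {
      est <- rbind(est, data.table(group = missing_lv, n = 0L,
                                   adjusted_mean = NA_real_,
                                   diff_vs_ref = NA_real_,
                                   p_value = NA_real_, outcome = lbl,
                                   sig = "missing"), fill = TRUE)
    }
    est
  })
  rbindlist(out)[, .(outcome, group, n, adjusted_mean, diff_vs_ref,
                     p_value, sig)]
}
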