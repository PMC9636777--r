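test_that("propensity scores: no-information and closed-form 2x2 oracle", {
  ## identical covariates -> scores equal the group prevalence
  d0 <- data.table(age_at_index = 40, white = 1L, private_insurance = 1L,
                   base_inpatient = 0L, base_outpatient = 1L,
                   ns = rep(c(1L, 0L), c(30, 70)))
  ps0 <- estimate_propensity(d0, "ns")
  expect_equal(ps0$scores, rep(0.3, 100), tolerance = 1e-6)

  ## single binary covariate: fitted probabilities equal the cell means
  d1 <- data.table(x = rep(c(0L, 1L), c(40, 60)),
                   ns = c(rbinom(40, 1, 0) + rep(c(0L, 1L), c(30, 10)),
                          rep(c(0L, 1L), c(20, 40))))
  ps1 <- estimate_propensity(d1, "ns", covariates = "x")
  expect_equal(unique(round(ps1$scores[d1$x == 0], 10)), 10 / 40)
  expect_equal(unique(round(ps1$scores[d1$x == 1], 10)), 40 / 60)

  ## perfect separation is reported
  d2 <- data.table(x = c(rep(0, 20), rep(1, 20)),
                   ns = c(rep(0L, 20), rep(1L, 20)))
  expect_warning(estimate_propensity(d2, "ns", covariates = "x"),
                 "separation")
})

test_that("planted confounding separates the score distributions", {
  tb <- small_sim(n = 1500, seed = 13)
  asm <- assemble_analysis(tb)
  ps <- estimate_propensity(asm$data, "ns", ps_covariates("susceptibility"))
  ks <- suppressWarnings(
    stats::ks.test(ps$scores[asm$data$ns == 1],
                   ps$scores[asm$data$ns == 0])$statistic)
  expect_gt(unname(ks), 0.05)
})

test_that("greedy 1:1 matching follows the hand-traced assignment", {
  ## identical score sets -> every treated matched at distance 0
  sc <- rep(c(0.2, 0.4, 0.6), 2)
  tr <- rep(c(TRUE, FALSE), each = 3)
  m <- match_1to1(sc, tr, ids = letters[1:6], seed = 1)
  expect_identical(nrow(m$pairs), 3L)
  expect_equal(m$pairs$distance, rep(0, 3))

  ## well-separated 3v3: nearest-neighbour result is order-independent,
  ## equal to the enumerated assignment
  lgt <- function(l) plogis(l)
  sc2 <- lgt(c(0, 5, 10, 0.4, 5.4, 10.4))
  tr2 <- rep(c(TRUE, FALSE), each = 3)
  for (seed in 1:5) {
    m2 <- match_1to1(sc2, tr2, ids = c("t1", "t2", "t3", "c1", "c2", "c3"),
                     caliper = Inf, seed = seed)
    got <- m2$pairs[order(treated_id)]
    expect_identical(got$control_id, c("c1", "c2", "c3"))
    expect_equal(got$distance, rep(0.4, 3), tolerance = 1e-9)
  }

  ## zero caliper with no exact ties -> no pairs
  m3 <- match_1to1(c(0.1, 0.9), c(TRUE, FALSE), caliper = 0, seed = 1)
  expect_identical(nrow(m3$pairs), 0L)
  expect_error(match_1to1(c(0.5, 0.5), c(TRUE, TRUE)), "non-empty")

  ## validity: ids unique, arms equal, within caliper
  tb <- small_sim(n = 800, seed = 23)
  asm <- assemble_analysis(tb)
  ps <- estimate_propensity(asm$data, "ns")
  mm <- match_1to1(ps$scores, asm$data$ns == 1, ids = asm$data$patient_id,
                   seed = 7)
  ids <- c(mm$pairs$treated_id, mm$pairs$control_id)
  expect_identical(anyDuplicated(ids), 0L)
  expect_true(all(mm$pairs$distance <= mm$caliper))
  ## deterministic given seed
  mm2 <- match_1to1(ps$scores, asm$data$ns == 1, ids = asm$data$patient_id,
                    seed = 7)
  expect_identical(mm$pairs, mm2$pairs)
})

test_that("SMD matches manual arithmetic and handles degenerate variance", {
  expect_equal(standardized_mean_difference(c(1, 2, 3, 1, 2, 3),
                                            rep(c("a", "b"), each = 3)), 0)
  ## means 0 and 1, unit variances
  x <- c(-1, 0, 1, 0, 1, 2)
  g <- rep(c("a", "b"), each = 3)
  expect_equal(standardized_mean_difference(x, g), 1)
  ## toy vectors, hand-computed: means 2 and 5, vars 1 and 4 -> 3/sqrt(2.5)
  y <- c(1, 2, 3, 3, 5, 7)
  expect_equal(standardized_mean_difference(y, g), 3 / sqrt(2.5))
  ## binary covariate uses p(1-p)
  b <- c(1, 1, 0, 0, 0, 0, 1, 1, 1, 0)
  gb <- rep(c("a", "b"), each = 5)
  p1 <- 0.4; p2 <- 0.6
  expect_equal(standardized_mean_difference(b, gb),
               abs(p1 - p2) / sqrt((p1 * (1 - p1) + p2 * (1 - p2)) / 2))
  ## zero pooled variance
  expect_equal(standardized_mean_difference(rep(1, 6), g), 0)
  expect_warning(
    out <- standardized_mean_difference(rep(c(0, 1), each = 3), g),
    "undefined")
  expect_identical(out, Inf)
})

test_that("matching improves covariate balance under planted confounding", {
  tb <- small_sim(n = 2000, seed = 31)
  asm <- assemble_analysis(tb)
  ps <- estimate_propensity(asm$data, "ns")
  mc <- match_1to1(ps$scores, asm$data$ns == 1, ids = asm$data$patient_id,
                   seed = 3)
  bt <- balance_table(asm$data, ps_covariates("susceptibility"), "ns", mc)
  expect_lt(mean(bt$smd_post), mean(bt$smd_pre))
  ## arms exactly equal-sized
  expect_identical(length(unique(mc$pairs$treated_id)),
                   length(unique(mc$pairs$control_id)))
})

test_that("gamma cost model: null, scale equivariance, zero handling", {
  set.seed(4)
  d <- data.table(cost = rgamma(400, 2, scale = 500),
                  grp = factor(rep(c("a", "b"), 200)))
  d[, cost2 := cost]  # identical outcomes in both groups by construction
  r0 <- fit_cost_model(d, "cost", "grp")
  expect_equal(r0$estimates[group == "b", diff_vs_ref],
               mean(d[grp == "b", cost]) - mean(d[grp == "a", cost]),
               tolerance = 1e-6)
  ## identical outcomes -> difference ~0: force exact symmetry
  dd <- data.table(cost = rep(rgamma(100, 2, scale = 300), 2),
                   grp = factor(rep(c("a", "b"), each = 100)))
  rr <- fit_cost_model(dd, "cost", "grp")
  expect_equal(rr$estimates[group == "b", diff_vs_ref], 0, tolerance = 1e-8)
  expect_equal(unname(coef(rr$model)["grpb"]), 0, tolerance = 1e-8)
  ## log-link equivariance: scaling costs by c scales the difference by c
  d3 <- copy(d)[, cost := cost * 3]
  r3 <- fit_cost_model(d3, "cost", "grp")
  expect_equal(r3$estimates$adjusted_mean, 3 * r0$estimates$adjusted_mean,
               tolerance = 1e-6)
  ## zeros lifted to the offset, or dropped on request
  dz <- copy(d)[1:5, cost := 0]
  rz <- fit_cost_model(dz, "cost", "grp")
  expect_true(rz$converged)
  rzd <- fit_cost_model(dz, "cost", "grp", drop_zeros = TRUE)
  expect_identical(sum(rzd$estimates$n), nrow(d) - 5L)
  expect_identical(r0$family, "Gamma")
  expect_identical(r0$link, "log")
})

test_that("stratified report covers all groups and flags empty ones", {
  tb <- small_sim(n = 900, seed = 41)
  asm <- assemble_analysis(tb)
  rep4 <- stratified_cost_report(asm$data)
  expect_setequal(unique(rep4$group), exposure_levels())
  expect_identical(nrow(rep4), 8L)  # 4 groups x 2 outcomes
  ref <- rep4[group == "S_app"]
  expect_equal(ref$diff_vs_ref, c(0, 0))
  ## degenerate: a group with n = 0 is flagged missing, no crash
  sub <- asm$data[exposure_group != "NS_app"]
  sub[, exposure_group := droplevels(exposure_group)]
  rep3 <- stratified_cost_report(sub)
  expect_identical(rep3[group == "NS_app" & outcome == "all_cause", sig],
                   "missing")
  ## permuting exposure labels destroys the planted effect
  perm <- copy(asm$data)
  set.seed(8)
  perm[, exposure_group := sample(exposure_group)]
  rp <- stratified_cost_report(perm)
  est <- rp[outcome == "all_cause" & group != "S_app", diff_vs_ref]
  truth <- rep4[outcome == "all_cause" & group == "NS_inapp_sub",
                diff_vs_ref]
  expect_lt(max(abs(est)), abs(truth))
})
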