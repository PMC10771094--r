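test_that("QC keeps wide-ranging fliers and drops cage-shy or grounded bats", {
  cage <- cage_geometry()
  wide <- toy_track("w", list(acclimation = runif(50, 20, 30),
                              control1 = runif(200, 10, 12),
                              combined = runif(200, 48, 50)))
  expect_true(qc_filter(wide, cage)$keep)   # span ~40 m > 30.1 m
  flat <- toy_track("f", list(acclimation = rep(15, 50),
                              control1 = rep(15, 200),
                              combined = rep(15, 200)))
  qf <- qc_filter(flat, cage)
  expect_false(qf$keep)
  expect_equal(qf$reason, "cage use <= 50%")
  # a span exactly at half the cage is exclusionary
  edge <- toy_track("e", list(acclimation = c(10, 20),
                              control1 = c(10, 10 + 30.1)))
  qe <- qc_filter(edge, cage)
  expect_equal(qe$span_m, 30.1)
  expect_false(qe$keep)
  # no acclimation flight
  late <- toy_track("l", list(control1 = runif(100, 1, 55)))
  expect_equal(qc_filter(late, cage)$reason, "no acclimation flight")
  expect_equal(qc_filter(wide[0, ], cage)$reason, "no flight")
})

test_that("period quantiles match the sort-and-interpolate oracle", {
  tr <- toy_track("q", list(control1 = as.numeric(0:100)))
  pq <- period_quantiles(tr, taus = 0.5, q_min = 10)
  expect_equal(pq$value, 50)
  # property: random small samples, random taus, 1000 cases
  set.seed(42)
  for (i in 1:1000) {
    n <- sample(5:40, 1)
    x <- runif(n, 0, 60)
    tau <- runif(1, 0.01, 0.99)
    tr <- toy_track("q", list(control1 = x))
    pq <- period_quantiles(tr, taus = tau, q_min = 2)
    expect_equal(pq$value, quantile_oracle(x, tau))
  }
  # 37-value set at tau = 0.25 against the oracle
  x <- withr::with_seed(7, runif(37, 0, 60))
  pq <- period_quantiles(toy_track("q", list(high = x)), taus = 0.25,
                         q_min = 10)
  expect_equal(pq$value, quantile_oracle(x, 0.25))
  # all-equal distances give that value at every tau
  cn <- toy_track("c", list(control1 = rep(7, 150)))
  pqc <- period_quantiles(cn, taus = c(.1, .5, .9))
  expect_true(all(pqc$value == 7))
  # under-observed periods go NA with a warning
  expect_warning(
    pqs <- period_quantiles(toy_track("s", list(control1 = 1:5)),
                            taus = 0.5, q_min = 100),
    "set NA")
  expect_true(is.na(pqs$value))
})

test_that("treatment effects average per-bat quantile differences", {
  # identical treatment and control distances: zero at every tau
  same <- dplyr::bind_rows(lapply(c("a", "b", "c"), function(id) {
    x <- withr::with_seed(match(id, letters), runif(300, 5, 55))
    toy_track(id, list(control1 = x, high = x))
  }))
  pq <- period_quantiles(same, taus = c(.1, .5, .9))
  for (tv in c(.1, .5, .9)) {
    eff <- treatment_effect(pq, "high", tv, B = 200)
    expect_equal(eff$estimate, 0)
  }
  # a uniform +10 shift of all order statistics: estimate 10, se 0
  shift <- dplyr::bind_rows(lapply(c("a", "b"), function(id) {
    toy_track(id, list(control1 = as.numeric(1:100),
                       combined = as.numeric(11:110)))
  }))
  pqs <- period_quantiles(shift, taus = c(.1, .25, .5, .75, .9))
  for (tv in c(.1, .25, .5, .75, .9)) {
    eff <- treatment_effect(pqs, "combined", tv, B = 500)
    expect_equal(eff$estimate, 10)
    expect_equal(eff$se, 0)
    expect_true(eff$significant)
  }
  # single bat: estimate only, uncertainty missing
  solo <- period_quantiles(toy_track("a", list(control1 = 1:200,
                                               low = 21:220)),
                           taus = 0.5)
  es <- treatment_effect(solo, "low", 0.5)
  expect_equal(es$estimate, 20)
  expect_true(is.na(es$se) && is.na(es$p))
})

test_that("effects are equivariant under a constant treatment shift", {
  base <- lapply(1:6, function(i) {
    withr::with_seed(i, list(control1 = runif(200, 5, 50),
                             low = runif(200, 10, 55)))
  })
  tr0 <- dplyr::bind_rows(purrr::imap(base, ~toy_track(paste0("b", .y), .x)))
  tr5 <- dplyr::bind_rows(purrr::imap(base, function(v, i) {
    toy_track(paste0("b", i), list(control1 = v$control1, low = v$low + 5))
  }))
  for (tv in c(.25, .5, .9)) {
    e0 <- treatment_effect(period_quantiles(tr0, taus = tv), "low", tv,
                           B = 300, seed = 2)
    e5 <- treatment_effect(period_quantiles(tr5, taus = tv), "low", tv,
                           B = 300, seed = 2)
    expect_equal(e5$estimate, e0$estimate + 5)
    expect_equal(e5$se, e0$se)
  }
})

test_that("control-consistency ANOVA matches hand-computed sums of squares", {
  # identical control columns: no period variance
  ident <- dplyr::bind_rows(lapply(1:4, function(i) {
    toy_track(paste0("b", i), list(control1 = rep(i * 2, 120),
                                   control2 = rep(i * 2, 120),
                                   control3 = rep(i * 2, 120)))
  }))
  pq <- period_quantiles(ident, taus = 0.5)
  tab <- control_consistency(pq, 0.5)
  expect_equal(tab$statistic[tab$term == "period"], 0)
  expect_equal(tab$p.value[tab$term == "period"], 1)

  # 4-bat toy table against textbook two-way (bat x period) formulas
  vals <- matrix(c(10, 12, 11,
                   20, 19, 22,
                   15, 14, 16,
                   30, 33, 29), nrow = 4, byrow = TRUE)
  toy <- dplyr::bind_rows(lapply(1:4, function(i) {
    toy_track(paste0("b", i), list(control1 = rep(vals[i, 1], 120),
                                   control2 = rep(vals[i, 2], 120),
                                   control3 = rep(vals[i, 3], 120)))
  }))
  pq2 <- period_quantiles(toy, taus = 0.5)
  tab2 <- control_consistency(pq2, 0.5)
  grand <- mean(vals)
  ss_bat <- 3 * sum((rowMeans(vals) - grand)^2)
  ss_per <- 4 * sum((colMeans(vals) - grand)^2)
  ss_tot <- sum((vals - grand)^2)
  ss_res <- ss_tot - ss_bat - ss_per
  f_hand <- (ss_per / 2) / (ss_res / 6)
  expect_equal(tab2$sumsq[tab2$term == "period"], ss_per)
  expect_equal(tab2$sumsq[tab2$term == "Residuals"], ss_res)
  expect_equal(tab2$statistic[tab2$term == "period"], f_hand)
  expect_equal(tab2$p.value[tab2$term == "period"],
               pf(f_hand, 2, 6, lower.tail = FALSE))

  # location invariance: adding a constant to every value leaves F unchanged
  toy10 <- dplyr::mutate(toy, distance_m = distance_m + 10)
  tab3 <- control_consistency(period_quantiles(toy10, taus = 0.5), 0.5)
  expect_equal(tab3$statistic[tab3$term == "period"], f_hand)
})

test_that("factorial ANOVA matches hand computation on a balanced toy", {
  # balanced 2x2, 3 bats per cell; Type II equals textbook SS when balanced
  cellmeans <- c(FF = 10, FS = 14, MF = 11, MS = 19)
  eff <- tibble::tibble(
    bat_id = paste0("b", 1:12),
    sex = rep(c("F", "F", "M", "M"), each = 3),
    season = rep(c("fall", "spring", "fall", "spring"), each = 3),
    effect = rep(cellmeans, each = 3) + rep(c(-1, 0, 1), 4)
  )
  res <- group_anova(eff)
  m <- matrix(cellmeans, 2, byrow = TRUE)  # rows sex F/M, cols fall/spring
  grand <- mean(m)
  ss_sex <- 6 * sum((rowMeans(m) - grand)^2)
  ss_sea <- 6 * sum((colMeans(m) - grand)^2)
  ss_int <- 3 * sum((m - outer(rowMeans(m) - grand, colMeans(m) - grand,
                               "+") - grand)^2)
  ss_res <- sum(rep(c(-1, 0, 1), 4)^2)
  tab <- res$anova
  expect_equal(tab$sumsq[tab$term == "sex"], ss_sex)
  expect_equal(tab$sumsq[tab$term == "season"], ss_sea)
  expect_equal(tab$sumsq[tab$term == "sex:season"], ss_int)
  expect_equal(tab$statistic[tab$term == "sex"],
               (ss_sex / 1) / (ss_res / 8))
  expect_true(res$interaction)
  # contrasts are oriented with the larger group first
  ctr <- res$contrasts
  sea <- ctr[ctr$factor == "season", ]
  expect_equal(sea$group_a, "spring")
  expect_equal(sea$difference_m, mean(m[, 2]) - mean(m[, 1]))
})

test_that("degenerate and unbalanced factorial designs are handled", {
  # all observations equal: every F is 0, p is 1
  flat <- tibble::tibble(bat_id = paste0("b", 1:8),
                         sex = rep(c("F", "M"), 4),
                         season = rep(c("fall", "spring"), each = 4),
                         effect = 3)
  res <- group_anova(flat)
  expect_true(all(res$anova$statistic[res$anova$term != "Residuals"] == 0))
  expect_true(all(res$anova$p.value[res$anova$term != "Residuals"] == 1))
  # an empty cell forbids the interaction by name
  nospring <- tibble::tibble(bat_id = paste0("b", 1:9),
                             sex = c(rep("F", 3), rep("M", 6)),
                             season = c(rep("fall", 6), rep("spring", 3)),
                             effect = rnorm(9))
  expect_error(group_anova(nospring, include_interaction = TRUE),
               class = "batcage_config_error")
  auto <- group_anova(nospring)
  expect_false(auto$interaction)
  expect_false("sex:season" %in% auto$anova$term)
})

test_that("the Bonferroni rule reports truncated thresholds", {
  b3 <- bonferroni_threshold(0.05, 3)
  expect_equal(b3$reported, 0.016)
  expect_equal(b3$exact, 0.05 / 3)
  expect_equal(bonferroni_threshold(0.05, 1)$reported, 0.05)
  expect_equal(bonferroni_threshold(0.05, 5)$reported, 0.01)
  expect_equal(bonferroni_threshold(0.03, 1)$exact, 0.03)
})

test_that("bat_effects joins quantile differences with metadata", {
  tracks <- dplyr::bind_rows(
    toy_track("b1", list(control1 = 1:100, high = 11:110)),
    toy_track("b2", list(control1 = 1:100, high = 31:130)))
  pq <- period_quantiles(tracks, taus = 0.5)
  meta <- tibble::tibble(bat_id = c("b1", "b2"), sex = c("F", "M"),
                         season = c("fall", "fall"))
  be <- bat_effects(pq, meta, "high", 0.5)
  expect_equal(sort(be$effect), c(10, 30))
})
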