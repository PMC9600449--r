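clin_row <- function(patient_id = "P1", relapse_flag = FALSE,
                     time_to_relapse_months = NA_real_,
                     follow_up_months = 36, death_cause = "alive") {
  tibble::tibble(patient_id = patient_id, treatment = "systemic",
                 response = "CR", relapse_flag = relapse_flag,
                 time_to_relapse_months = time_to_relapse_months,
                 follow_up_months = follow_up_months,
                 death_cause = death_cause, myc_rearranged = NA)
}

test_that("endpoint construction encodes OS/DSS/PFS semantics and 5-year censoring", {
  clin <- bind_rows(
    clin_row("alive80", follow_up_months = 80),
    clin_row("lymph14", follow_up_months = 14, death_cause = "lymphoma"),
    clin_row("other45", follow_up_months = 45, death_cause = "other"),
    clin_row("rel20", relapse_flag = TRUE, time_to_relapse_months = 20,
             follow_up_months = 50))
  os <- build_endpoint(clin, "OS")
  dss <- build_endpoint(clin, "DSS")
  pfs <- build_endpoint(clin, "PFS")
  get <- function(d, id) d[d$patient_id == id, ]

  # administrative censoring at 60 months
  expect_equal(get(os, "alive80")$time_months, 60)
  expect_false(get(os, "alive80")$event)
  # lymphoma death is an event on every endpoint
  expect_true(get(os, "lymph14")$event && get(dss, "lymph14")$event &&
                get(pfs, "lymph14")$event)
  expect_equal(get(pfs, "lymph14")$time_months, 14)
  # other-cause death: OS event, DSS censored at the death time
  expect_true(get(os, "other45")$event)
  expect_false(get(dss, "other45")$event)
  expect_equal(get(dss, "other45")$time_months, 45)
  # relapse drives PFS, not OS
  expect_true(get(pfs, "rel20")$event)
  expect_equal(get(pfs, "rel20")$time_months, 20)
  expect_false(get(os, "rel20")$event)
})

test_that("inconsistent explicit event flags are rejected", {
  clin <- mutate(clin_row(death_cause = "lymphoma", follow_up_months = 14),
                 os_event = FALSE)
  expect_error(build_endpoint(clin, "OS"), "without os_event")
  clin2 <- mutate(clin_row(death_cause = "lymphoma", follow_up_months = 14),
                  dss_event = FALSE)
  expect_error(build_endpoint(clin2, "DSS"), "without dss_event")
})

test_that("KM estimator matches closed forms and a hand-computed table", {
  # no censoring: steps 0.75 / 0.5 / 0.25 / 0, median 2
  d <- tibble::tibble(time_months = 1:4, event = TRUE)
  km <- km_estimate(d)
  expect_equal(tidy(km)$surv, c(0.75, 0.5, 0.25, 0))
  expect_equal(glance(km)$median_months, 2)

  # all censored: flat at 1, median undefined
  d2 <- tibble::tibble(time_months = c(5, 8, 13), event = FALSE)
  km2 <- km_estimate(d2)
  expect_true(all(tidy(km2)$surv == 1))
  expect_true(is.na(glance(km2)$median_months))

  # hand-computed product-limit table: events {3,5,9}, censored {4,7,10}
  d3 <- tibble::tibble(time_months = c(3, 4, 5, 7, 9, 10),
                       event = c(TRUE, FALSE, TRUE, FALSE, TRUE, FALSE))
  steps <- tidy(km_estimate(d3))
  ev <- steps[steps$n_event > 0, ]
  expect_equal(ev$time, c(3, 5, 9))
  expect_equal(ev$surv, c(5 / 6, 5 / 6 * 3 / 4, 5 / 6 * 3 / 4 * 1 / 2))
})

test_that("without censoring KM equals the empirical survival function", {
  set.seed(14)
  t <- round(rexp(40, 0.05), 2)
  km <- tidy(km_estimate(tibble::tibble(time_months = t, event = TRUE)))
  ecdf_surv <- vapply(km$time, function(x) mean(t > x), numeric(1))
  expect_equal(km$surv, ecdf_surv)
})

test_that("log-rank is null on identical groups and powered under HR 6.52", {
  d <- tibble::tibble(time_months = rep(c(3, 6, 9, 12), 2),
                      event = rep(c(TRUE, TRUE, FALSE, TRUE), 2))
  res <- logrank_test(d, rep(c("a", "b"), each = 4))
  expect_equal(res$statistic, 0, tolerance = 1e-12)
  expect_equal(res$p_value, 1, tolerance = 1e-12)
  expect_error(logrank_test(d, rep("a", 8)), "two non-empty groups")

  set.seed(100)
  n <- 500
  grp <- rep(c(TRUE, FALSE), each = n)
  t <- c(rexp(n, 0.1 * 6.52), rexp(n, 0.1))
  res2 <- logrank_test(tibble::tibble(time_months = t, event = TRUE), grp)
  expect_lt(res2$p_value, 0.001)
})

test_that("per-gene Cox screen skips untestable genes and adjusts monotonically", {
  cov <- tibble::tibble(patient_id = sprintf("P%03d", 1:120),
                        EVERYONE = TRUE,
                        SINGLETON = c(TRUE, rep(FALSE, 119)),
                        HIST1H1E = rep(c(TRUE, FALSE), c(30, 90)),
                        NULL1 = rep(c(TRUE, FALSE), 60),
                        NULL2 = rep(c(FALSE, TRUE), 60))
  cfg <- sim_config(seed = 6, hazard_log_hr = c(HIST1H1E = log(6.52)))
  clin <- simulate_survival(cfg, cov)
  os <- build_endpoint(clin, "OS")
  res <- cox_per_gene(os, cov)
  expect_setequal(attr(res, "skipped_genes"), c("EVERYONE", "SINGLETON"))
  expect_false("EVERYONE" %in% res$gene)
  expect_true(all(res$p_adjusted >= res$p_raw, na.rm = TRUE))
  expect_true(all(res$p_adjusted <= 1, na.rm = TRUE))
  expect_equal(res$p_adjusted, sort(res$p_adjusted))
  expect_true(all(res$ci_lower <= res$hr & res$hr <= res$ci_upper,
                  na.rm = TRUE))
  # the true risk gene tops the screen with an elevated hazard
  expect_equal(res$gene[1], "HIST1H1E")
  expect_gt(res$hr[1], 1)
})

test_that("Cox confidence intervals achieve near-nominal coverage", {
  set.seed(7)
  hits <- 0
  reps <- 100
  for (i in 1:reps) {
    n <- 200
    x <- rbinom(n, 1, 0.4) == 1
    t <- rexp(n, 0.05 * ifelse(x, 2.5, 1))
    d <- tibble::tibble(patient_id = as.character(1:n),
                        time_months = t, event = TRUE)
    res <- cox_per_gene(d, tibble::tibble(patient_id = as.character(1:n),
                                          G = x))
    if (res$ci_lower[1] <= 2.5 && 2.5 <= res$ci_upper[1]) hits <- hits + 1
  }
  expect_gte(hits / reps, 0.89)
  expect_lte(hits / reps, 0.99)
})
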