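test_that("kaplan_meier handles the textbook cases", {
  km <- kaplan_meier(c(2, 5, 9), c(0, 0, 0))
  expect_length(km$event_times, 0)
  expect_equal(km_survival_at(km, c(0, 3, 100)), c(1, 1, 1))

  km2 <- kaplan_meier(c(1, 2, 3), c(1, 1, 1))
  expect_equal(km2$survival, c(2 / 3, 1 / 3, 0))
  expect_equal(km2$at_risk, c(3L, 2L, 1L))

  expect_error(kaplan_meier(numeric(0), numeric(0)), "empty")
  expect_error(kaplan_meier(c(-1, 2), c(1, 1)), "negative")
  expect_error(kaplan_meier(c(1, 2), c(1, 2)), "0 or 1")
})

test_that("kaplan_meier equals the brute-force product-limit oracle", {
  for (seed in 1:5) {
    set.seed(seed)
    n <- sample(20:80, 1)
    times <- round(rexp(n, 0.2), 2)   # rounding forces ties
    events <- rbinom(n, 1, 0.6)
    km <- kaplan_meier(times, events)
    for (t in c(km$event_times, 0.5, 4.4)) {
      expect_equal(km_survival_at(km, t), km_oracle(times, events, t),
                   tolerance = 1e-12)
    }
  }
})

test_that("kaplan_meier matches survival::survfit", {
  skip_if_not_installed("survival")
  set.seed(10)
  times <- round(rexp(150, 0.2), 1)
  events <- rbinom(150, 1, 0.7)
  km <- kaplan_meier(times, events)
  sf <- summary(survival::survfit(survival::Surv(times, events) ~ 1),
                times = km$event_times)
  expect_equal(km$survival, sf$surv, tolerance = 1e-12)
  expect_equal(km$at_risk, sf$n.risk)
})

test_that("logrank is zero on symmetric duplicated data", {
  times <- c(1, 3, 4, 7); events <- c(1, 0, 1, 1)
  lr <- logrank(c(times, times), c(events, events),
                rep(c("a", "b"), each = 4))
  expect_equal(lr$chi_square, 0, tolerance = 1e-12)
  expect_equal(lr$p_value, 1)
  expect_equal(sum(lr$observed), sum(lr$expected), tolerance = 1e-9)
})

test_that("logrank matches survival::survdiff on random cohorts", {
  skip_if_not_installed("survival")
  for (seed in 1:4) {
    set.seed(seed)
    n <- 100
    times <- round(rexp(n, 0.2), 1)
    events <- rbinom(n, 1, 0.7)
    groups <- rbinom(n, 1, 0.4)
    lr <- logrank(times, events, groups)
    sd_ <- survival::survdiff(survival::Surv(times, events) ~ groups)
    expect_equal(lr$chi_square, sd_$chisq, tolerance = 1e-10)
    expect_equal(unname(lr$observed), unname(sd_$obs), tolerance = 1e-10)
    expect_equal(unname(lr$expected), unname(sd_$exp), tolerance = 1e-10)
    expect_equal(sum(lr$observed), sum(lr$expected), tolerance = 1e-9)
  }
})

test_that("logrank input validation", {
  expect_error(logrank(c(1, 2), c(1, 1), c("a", "a")), "two levels")
  expect_error(logrank(c(1, 2), c(0, 0), c("a", "b")), "no events")
})

test_that("logrank detects a strong hazard ratio", {
  # scaled down from the 500-seed design: 120 seeds, HR = 3, n = 200/200
  sig <- vapply(1:120, function(seed) {
    set.seed(seed)
    t1 <- rexp(200, 0.3); t2 <- rexp(200, 0.1)
    cens <- rexp(400, 0.05)
    times <- pmin(c(t1, t2), cens, 10)
    events <- as.integer(c(t1, t2) <= pmin(cens, 10))
    logrank(times, events, rep(1:2, each = 200))$p_value < 0.05
  }, logical(1))
  expect_gte(mean(sig), 0.9)
})

test_that("risk_table counts subjects still under observation", {
  set.seed(11)
  times <- round(rexp(60, 0.2), 1)
  events <- rbinom(60, 1, 0.6)
  km <- kaplan_meier(times, events)
  rt <- risk_table(km, c(0, 2, 5, max(times) + 1))
  expect_equal(rt$at_risk[1], 60)
  expect_equal(rt$at_risk[4], 0)
  for (i in seq_len(nrow(rt)))                 # counting oracle
    expect_equal(rt$at_risk[i], sum(times >= rt$time[i]))
  expect_error(risk_table(km, c(5, 2)), "ascending")
})

test_that("the screen reproduces the marker's own log-rank p", {
  co <- small_cohort(seed = 13, n = 150)
  h <- suppressMessages(harmonize_cohort(co$expression, co$clinical))
  screen <- per_gene_survival_screen(h$expression, h$clinical, "MARKER")
  strata <- suppressMessages(
    classify(h$expression$values["MARKER", h$clinical$sample_id],
             pooled_valley_threshold(
               list(h$expression$values["MARKER", ]), activity = TRUE)))
  lr <- logrank(h$clinical$dfs_time, h$clinical$dfs_event,
                strata$labels[h$clinical$sample_id])
  expect_identical(screen$method, "valley")
  expect_equal(screen$p_value, lr$p_value, tolerance = 1e-10)
})

test_that("a survival-independent gene rejects at ~5%", {
  rejected <- vapply(1:200, function(seed) {
    set.seed(seed)
    n <- 120
    g <- c(rnorm(n / 2, 0, 0.3), rnorm(n / 2, 2, 0.3))  # bimodal, no effect
    times <- pmin(rexp(n, 0.15), 10)
    events <- as.integer(times < 10)
    lab <- suppressMessages(markstrat:::dichotomize_gene(g)$labels)
    logrank(times, events, lab)$p_value < 0.05
  }, logical(1))
  expect_lt(abs(mean(rejected) - 0.05), 0.03)
})

test_that("multi-cohort screen flags match brute-force recomputation", {
  skip_if_not_installed("survival")
  cohorts <- generate_multi_cohort(
    lapply(1:3, function(i) cohort_config(n_samples = 150, n_genes = 8,
                                          module_genes = 4, seed = 17 + i)))
  genes <- cohorts[[1]]$expression$feature_ids
  screens <- lapply(cohorts, function(co) {
    h <- suppressMessages(harmonize_cohort(co$expression, co$clinical))
    per_gene_survival_screen(h$expression, h$clinical, genes)
  })
  flagged <- flag_significant(screens, level = 0.05, min_cohorts = 2)

  # oracle: same dichotomy, independent log-rank engine, explicit counting
  count_sig <- sapply(genes, function(g) {
    sum(vapply(cohorts, function(co) {
      h <- suppressMessages(harmonize_cohort(co$expression, co$clinical))
      lab <- suppressMessages(
        markstrat:::dichotomize_gene(h$expression$values[g, h$clinical$sample_id]))
      lab <- lab$labels[h$clinical$sample_id]
      sd_ <- survival::survdiff(
        survival::Surv(h$clinical$dfs_time, h$clinical$dfs_event) ~ lab)
      (1 - pchisq(sd_$chisq, 1)) < 0.05
    }, logical(1)))
  })
  oracle_set <- sort(genes[count_sig >= 2])
  expect_setequal(flagged$gene[flagged$significant], oracle_set)
})
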