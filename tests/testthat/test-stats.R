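test_that("case aggregation is the plain mean with bookkeeping", {
  expect_equal(aggregate_case(c(1, 2, 3)), list(value = 2, n = 3))
  expect_equal(aggregate_case(5), list(value = 5, n = 1))
  expect_equal(aggregate_case(c(3, 1, 2)), aggregate_case(c(1, 2, 3)))
  expect_error(aggregate_case(numeric(0)), "no section values")
})

test_that("Grubbs flags the constructed outlier at alpha 0.2 and matches the
           t-quantile formula", {
  g <- grubbs_outlier(c(10, 10, 10, 10, 100), alpha = 0.2)
  expect_identical(g$index, 5L)
  expect_equal(g$G, 1.789, tolerance = 1e-3)
  expect_equal(g$critical, oracle_grubbs_critical(5, 0.2), tolerance = 1e-12)

  expect_true(is.na(grubbs_outlier(rep(4, 6))$index))
  # symmetric extremes: G = 100 / 70.7 = 1.414 stays below the alpha = 0.2
  # critical value (1.602), so nothing is flagged ...
  sym <- grubbs_outlier(c(-100, 0, 0, 0, 100), alpha = 0.2)
  expect_equal(sym$G, sqrt(2), tolerance = 1e-9)
  expect_true(is.na(sym$index))
  # ... and when the critical value drops below G, only the first of the two
  # tied extremes is returned (single-outlier test, first-index tie-break)
  loose <- grubbs_outlier(c(-100, 0, 0, 0, 100), alpha = 0.7)
  expect_identical(loose$index, 1L)
  expect_error(grubbs_outlier(c(1, 2)), "at least 3")
})

test_that("Mann-Whitney reproduces exhaustive enumeration for all small
           samples", {
  r <- mann_whitney(c(1, 2), c(3, 4))
  expect_equal(r$statistic, 0)
  expect_equal(r$p, 2 / 6, tolerance = 1e-12)
  expect_identical(r$method, "exact enumeration")

  same <- mann_whitney(c(5, 6, 7), c(5, 6, 7))
  expect_equal(same$p, 1)

  withr::with_seed(7, {
    for (n1 in 1:5) {
      n2s <- seq(n1, 10 - n1)
      for (n2 in n2s) {
        vals <- sample(100, n1 + n2) # distinct, no ties
        a <- vals[seq_len(n1)]; b <- vals[-seq_len(n1)]
        expect_equal(mann_whitney(a, b)$p, oracle_mw_p(a, b),
                     tolerance = 1e-12,
                     info = sprintf("n1=%d n2=%d", n1, n2))
      }
    }
  })

  withr::with_seed(8, {
    a <- rnorm(20); b <- rnorm(20) + 1000
  })
  expect_lt(mann_whitney(a, b)$p, 0.001)
})

test_that("Welch t and Pearson regression cover the textbook cases", {
  x <- c(1.2, 3.4, 2.2, 5.1)
  same <- welch_t(x, x)
  expect_equal(same$statistic, 0)
  expect_equal(same$p, 1)

  eps <- 1e-6
  near <- welch_t(c(0, 0, 0) + c(-eps, 0, eps), c(1, 1, 1) + c(-eps, 0, eps))
  expect_lt(near$p, 1e-10) # p -> 0 as jitter -> 0

  xx <- c(1, 2, 3, 4, 5)
  fit <- pearson_linreg(xx, 2 * xx + 1)
  expect_equal(fit$r, 1)
  expect_equal(fit$slope, 2)
  expect_equal(fit$intercept, 1)
  expect_error(pearson_linreg(rep(2, 4), rnorm(4)), "zero variance")
})

test_that("two-way ANOVA: null balanced designs, Sidak algebra, and Type III
           = Type I on balanced data", {
  withr::with_seed(15, {
    d <- expand.grid(group = c("control", "ALS"),
                     level = c("cervical", "thoracic", "lumbar"),
                     rep = 1:6)
    d$value <- 10 + rnorm(nrow(d), 0, 1)
  })
  res <- two_way_anova(d, "value", "group", "level")
  expect_true(all(res$anova$p > 0.01))
  ph <- res$posthoc
  expect_true(all(ph$p_adj >= ph$p_raw - 1e-12, na.rm = TRUE))
  expect_true(all(ph$p_adj <= 1 & ph$p_adj >= 0))
  sk <- ph[ph$family == "sidak", ]
  expect_equal(sk$p_adj, 1 - (1 - sk$p_raw)^nrow(sk), tolerance = 1e-12)

  # balanced: Type III sums of squares match the sequential decomposition
  old <- options(contrasts = c("contr.sum", "contr.poly"))
  fit <- lm(value ~ group * level, data = d)
  type1 <- anova(fit)
  options(old)
  ss3 <- res$anova$ss[match(c("group", "level", "group:level"),
                            res$anova$term)]
  ss1 <- type1$`Sum Sq`[match(c("group", "level", "group:level"),
                              rownames(type1))]
  expect_equal(ss3, ss1, tolerance = 1e-8)
})

test_that("main-effect detection rate matches noncentral-F power within 5
           points", {
  # 2 x 3 balanced design, n = 10 per cell, sigma = 1, group effect +/- d/2
  d_eff <- 0.6
  n_cell <- 10
  n_sims <- 400
  cells <- expand.grid(group = c("g1", "g2"),
                       level = c("l1", "l2", "l3"), rep = seq_len(n_cell))
  shift <- ifelse(cells$group == "g1", -d_eff / 2, d_eff / 2)
  withr::with_seed(99, {
    hits <- vapply(seq_len(n_sims), function(i) {
      cells$value <- shift + rnorm(nrow(cells))
      r <- two_way_anova(cells, "value", "group", "level", posthoc = "sidak")
      r$anova$p[r$anova$term == "group"] < 0.05
    }, logical(1))
  })
  # closed-form power of the group main effect F(1, N - 6) test
  N <- nrow(cells)
  ncp <- N * (d_eff / 2)^2 # sum over cells of (cell shift)^2 / sigma^2
  power <- 1 - pf(qf(0.95, 1, N - 6), 1, N - 6, ncp = ncp)
  expect_lt(abs(mean(hits) - power), 0.05)
})

test_that("repeated-measures ANOVA requires a complete design and detects a
           within-subject effect", {
  withr::with_seed(31, {
    d <- expand.grid(case = paste0("s", 1:8),
                     leaked = c("leaked", "nonleaked"),
                     compartment = c("gray", "white"))
    d$value <- 100 + rnorm(nrow(d), 0, 1)
    d$value[d$leaked == "leaked" & d$compartment == "white"] <-
      d$value[d$leaked == "leaked" & d$compartment == "white"] - 6
  })
  res <- two_way_anova(d, "value", "leaked", "compartment",
                       repeated = "both", subject = "case")
  expect_true("f1:f2" %in% res$anova$term || any(grepl(":", res$anova$term)))
  ph <- res$posthoc
  white <- ph[ph$by == "white", ]
  expect_lt(white$p_adj, 0.05)

  expect_error(two_way_anova(d[-1, ], "value", "leaked", "compartment",
                             repeated = "both", subject = "case"),
               "complete")
  expect_error(two_way_anova(d, "value", "leaked", "compartment",
                             repeated = "both"), "subject")
})

test_that("the battery applies the Grubbs exclusion and reports control n
           5 -> 4", {
  withr::with_seed(55, {
    cases <- c(paste0("H", 1:5), paste0("MN", 1:13))
    groups <- rep(c("control", "ALS"), c(5, 13))
    rows <- list()
    for (i in seq_along(cases)) {
      for (lv in c("cervical", "thoracic", "lumbar")) {
        for (sct in 1:3) {
          base_hb <- if (groups[i] == "control") 100 else 200
          if (cases[i] == "H5") base_hb <- 3000 # constructed outlier
          rows[[length(rows) + 1L]] <- data.frame(
            case = cases[i], level = lv, section = sct,
            gm_hb = base_hb + rnorm(1, 0, 10),
            wm_hb = base_hb + rnorm(1, 0, 10),
            hb_total = base_hb + rnorm(1, 0, 10),
            gm_vessel_density = 100 + rnorm(1, 0, 5),
            wm_vessel_density = 80 + rnorm(1, 0, 5),
            neuron_density = if (groups[i] == "control") 30 else
              15 + rnorm(1, 0, 2),
            inclusion_load = ifelse(groups[i] == "control", 0, 2) +
              abs(rnorm(1, 0, 0.2))
          )
        }
      }
    }
    results <- do.call(rbind, rows)
  })
  metadata <- data.frame(case = cases, group = groups)
  bat <- run_cohort_battery(results, metadata)
  expect_identical(bat$excluded_case, "H5")
  expect_equal(bat$cohort_n$control, 4)
  expect_equal(bat$cohort_n$ALS, 13)
  expect_true(all(c("hb_total", "neuron_density",
                    "inclusion_load_pooled") %in% names(bat$tables)))
  # the pooled inclusion-load contrast is overwhelming by construction
  expect_lt(bat$tables$inclusion_load_pooled$p, 1e-6)
  # case values no longer contain the excluded control
  expect_false("H5" %in% bat$case_values$case)
})
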