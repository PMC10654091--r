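course <- function(subject, route, start, dur) {
  data.frame(subject_id = subject, route = route, start_day = start,
             duration_days = dur, stringsAsFactors = FALSE)
}

test_that("cumulative oral days is a union of covered days, clipped", {
  # no courses
  ev <- build_exposure_variables(course(character(0), character(0),
                                        integer(0), integer(0)),
                                 subjects = "A")
  expect_equal(ev$cumulative_oral_days, 0)
  expect_false(ev$used_at_birth)

  # one 10-day course
  ev <- build_exposure_variables(course("A", "oral", 100, 10))
  expect_equal(ev$cumulative_oral_days, 10)

  # overlapping courses days 5-14 and 10-19: union is 15 days, not 20
  log <- rbind(course("A", "oral", 5, 10), course("A", "oral", 10, 10))
  ev <- build_exposure_variables(log)
  expect_equal(ev$cumulative_oral_days, 15)
  # order of courses is irrelevant
  expect_equal(build_exposure_variables(log[2:1, ])$cumulative_oral_days, 15)

  # clipping at the cutoff day
  ev <- build_exposure_variables(course("A", "oral", 360, 10))
  expect_equal(ev$cumulative_oral_days, 5)
  expect_lte(build_exposure_variables(course("A", "oral", 0, 400))$
               cumulative_oral_days, 365)
})

test_that("topical courses are excluded and routes validated", {
  log <- rbind(course("A", "oral", 30, 5), course("A", "topical", 2, 20))
  ev <- build_exposure_variables(log)
  expect_equal(ev$cumulative_oral_days, 5)
  expect_false(ev$used_at_birth)   # topical at birth does not count
  expect_error(build_exposure_variables(course("A", "po", 1, 1)),
               "unknown route")
})

test_that("use at birth covers systemic courses in the birth window", {
  expect_true(build_exposure_variables(course("A", "IM", 3, 3))$used_at_birth)
  expect_true(build_exposure_variables(course("A", "oral", 0, 2))$used_at_birth)
  expect_false(build_exposure_variables(course("A", "IV", 30, 3))$used_at_birth)
})

test_that("recent and current use flags follow the 7-day window", {
  log <- course("A", "oral", 50, 5)   # days 50..54
  expect_true(recent_oral_use(log, day = 61)[["A"]])
  expect_false(recent_oral_use(log, day = 70)[["A"]])
  expect_true(current_oral_use(log, day = 52)[["A"]])
  expect_false(current_oral_use(log, day = 61)[["A"]])
})

test_that("Fisher exact matches the printed 2x2 result and the null", {
  p <- fisher_exact_2x2(rbind(c(3, 9), c(2, 58)))
  expect_equal(round(p, 2), 0.03)
  expect_equal(fisher_exact_2x2(rbind(c(0, 10), c(0, 10))), 1)
  expect_equal(fisher_exact_2x2(rbind(c(5, 0), c(0, 5))), 2 / 252,
               tolerance = 1e-10)
  expect_error(fisher_exact_2x2(rbind(c(-1, 1), c(1, 1))), "non-negative")
})

test_that("Fisher exact agrees with hypergeometric enumeration", {
  set.seed(61)
  for (i in 1:50) {
    tab <- matrix(rpois(4, 6), 2)
    expect_equal(fisher_exact_2x2(tab), oracle_fisher_two_sided(tab),
                 tolerance = 1e-9)
    expect_equal(fisher_exact_2x2(tab, "greater"),
                 oracle_fisher_greater(tab), tolerance = 1e-9)
  }
})

test_that("exposure log summary reports route composition", {
  log <- rbind(course(rep("A", 3), "oral", c(10, 30, 50), 5),
               course("B", "topical", 10, 5))
  s <- summarise_exposure_log(log)
  expect_equal(s$n_courses, 4)
  expect_equal(s$oral_percent, 75)
})

test_that("BH adjustment matches the step-up definition", {
  expect_equal(bh_adjust(0.2), 0.2)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(c(0.005, 0.04, 0.2)), c(0.015, 0.06, 0.2))
  expect_error(bh_adjust(c(0.5, 0)), "0, 1")
  expect_error(bh_adjust(c(0.5, 1.2)), "0, 1")
  set.seed(71)
  for (i in 1:20) {
    p <- runif(sample(2:50, 1))
    expect_equal(unname(bh_adjust(p)), oracle_bh(p), tolerance = 1e-12)
  }
})

test_that("double FDR reduces to BH for one group and matches the worked example", {
  p <- c(a = 0.01, b = 0.2, c = 0.04)
  one <- double_fdr(list(g = p))
  expect_equal(one$adjusted_p, bh_adjust(p))

  two <- double_fdr(list(G1 = c(h1 = 0.01, h2 = 0.04), G2 = c(h3 = 0.5)))
  expect_equal(unname(two$adjusted_p[c("h1", "h2", "h3")]),
               c(0.02, 0.04, 0.50))

  allone <- double_fdr(list(G1 = c(x = 1, y = 1), G2 = c(z = 1)))
  expect_true(all(allone$adjusted_p == 1))
  expect_error(double_fdr(list(G1 = numeric(0))), "empty")
})

test_that("double FDR dominates raw and within-group BH p-values", {
  set.seed(81)
  for (i in 1:20) {
    k <- sample(2:4, 1)
    groups <- lapply(seq_len(k), function(g) {
      p <- runif(sample(1:6, 1))
      stats::setNames(p, paste0("g", g, "h", seq_along(p)))
    })
    names(groups) <- paste0("G", seq_len(k))
    res <- double_fdr(groups)
    for (g in names(groups)) {
      raw <- groups[[g]]
      adj <- res$adjusted_p[names(raw)]
      expect_true(all(adj >= raw - 1e-12))
      expect_true(all(adj >= bh_adjust(raw) - 1e-12))
      expect_true(all(adj >= res$group_p[[g]] - 1e-12))
    }
  }
})

test_that("the default battery tests ten hypotheses in four groups", {
  co <- generate_cohort(small_cohort_config(seed = 5,
                                            assess_rate_1yr = 1))
  to <- titer_outcomes(co$titers)
  et <- exposure_test_suite(co$exposures, to$outcomes)
  expect_equal(nrow(et), 10)
  expect_setequal(unique(et$group),
                  c("cumulative_use", "recent_use", "current_use",
                    "use_at_birth"))
  expect_true(all(et$p_adjusted >= et$p_raw - 1e-12))
})
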