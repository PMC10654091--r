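test_that("the generator is deterministic for a fixed seed and config", {
  c1 <- generate_cohort(small_cohort_config(seed = 9))
  c2 <- generate_cohort(small_cohort_config(seed = 9))
  expect_identical(c1$titers, c2$titers)
  expect_identical(c1$exposures, c2$exposures)
  expect_identical(c1$features, c2$features)
  expect_identical(c1$metabolites, c2$metabolites)
  c3 <- generate_cohort(small_cohort_config(seed = 10))
  expect_false(identical(c1$titers, c3$titers))
})

test_that("a non-PSD correlation request names the offending parameters", {
  expect_error(cohort_config(intra_pcv_correlation = 0.05,
                             intra_dtap_correlation = 0.05,
                             cross_panel_correlation = 0.9),
               "positive semi-definite.*cross_panel_correlation")
  expect_error(cohort_config(lvr_rate = 1.4), "proportions")
})

test_that("the classifier recovers the designed LVR fraction", {
  cfg <- cohort_config(n_subjects = 72, lvr_rate = 12 / 72,
                       assess_rate_1yr = 1, assess_rate_2yr = 0,
                       visit_ages = c(61, 365), n_kos = 10, n_genera = 5,
                       n_otus = 5, n_metabolites = 5, n_modules = 2,
                       stool_depth = 500, nasal_depth = 500, seed = 17)
  co <- generate_cohort(cfg)
  cls <- classify_responders(co$titers, "1yr")
  n_lvr <- sum(cls$category == "LVR")
  # 3-binomial-SD band around the design value of 12
  expect_gte(n_lvr, 4)
  expect_lte(n_lvr, 20)
  # every designated low responder is labelled LVR (closed loop)
  gt <- co$ground_truth$subjects
  lab <- cls$category[match(gt$subject_id, cls$subject_id)]
  expect_true(all(lab[gt$lvr_1yr] == "LVR"))
})

test_that("exposure counts carry the configured ZIP components", {
  cfg <- small_cohort_config(seed = 23, n_subjects = 400,
                             lvr_rate = 0.5)
  co <- generate_cohort(cfg)
  gt <- co$ground_truth$subjects
  ev <- build_exposure_variables(co$exposures, subjects = gt$subject_id)
  expect_identical(ev$cumulative_oral_days, gt$true_cumulative_oral_days)
  # per-group ZIP fits recover the configured parameters
  for (g in c("NVR", "LVR")) {
    sel <- if (g == "LVR") gt$lvr_1yr else !gt$lvr_1yr
    fit <- zip_fit(ev$cumulative_oral_days[sel])
    n <- sum(sel)
    pi0 <- co$config$zip_pi[[g]]; lam0 <- co$config$zip_lambda[[g]]
    expect_lt(abs(fit$pi - pi0), 3 * sqrt(pi0 * (1 - pi0) / n) + 0.02)
    expect_lt(abs(fit$lambda - lam0),
              3 * sqrt(lam0 / (n * (1 - pi0))) + 0.1)
  }
})

test_that("non-zero exposure medians track the group lambdas", {
  set.seed(31)
  meds <- replicate(10, {
    nvr <- rzip(1000, 0.47, 10); lvr <- rzip(1000, 0.50, 28)
    c(median(nvr[nvr > 0]), median(lvr[lvr > 0]))
  })
  expect_lte(max(abs(meds[1, ] - 10)), 1)
  expect_lte(max(abs(meds[2, ] - 28)), 1)
})

test_that("zero planted effect leaves planted KOs uncorrelated", {
  co <- generate_cohort(small_cohort_config(seed = 29, n_subjects = 72,
                                            planted_ko_effect = 0))
  gt <- co$ground_truth
  meta <- co$samples[co$samples$sample_type == "stool_ko", ]
  meta$tp <- assign_timepoint(meta$age_days)
  m2 <- meta[!is.na(meta$tp) & meta$tp == "2mo", ]
  feat <- co$features$stool_ko[m2$sample_id, gt$planted_kos, drop = FALSE]
  score <- gt$subjects$composite_score[match(m2$subject_id,
                                             gt$subjects$subject_id)]
  rhos <- apply(feat, 2, function(v) cor(v, score, method = "spearman"))
  expect_lt(median(abs(rhos)), 0.2)
})

test_that("planted features exist in the emitted tables with the right sign", {
  co <- generate_cohort(small_cohort_config(seed = 37))
  gt <- co$ground_truth
  expect_true(all(gt$planted_kos %in% colnames(co$features$stool_ko)))
  expect_true(gt$planted_metabolite %in% colnames(co$metabolites))
  expect_true(all(gt$planted_kos %in%
                    co$module_map$ko_id[co$module_map$module_id ==
                                          gt$planted_module]))
  # metabolite effect is negative by default
  meta <- co$samples[co$samples$sample_type == "metabolite", ]
  score <- gt$subjects$composite_score[match(meta$subject_id,
                                             gt$subjects$subject_id)]
  rho <- cor(co$metabolites[meta$sample_id, gt$planted_metabolite], score,
             method = "spearman")
  expect_lt(rho, 0)
})

test_that("write and read round-trip a cohort through TSV", {
  co <- generate_cohort(small_cohort_config(seed = 43))
  dir <- withr::local_tempdir()
  manifest <- write_cohort(co, dir)
  expect_true(all(c("titers.tsv", "exposures.tsv", "samples.tsv",
                    "features_stool_ko.tsv", "ground_truth.json") %in%
                    manifest$file))
  expect_equal(manifest$rows[manifest$file == "titers.tsv"], nrow(co$titers))
  back <- read_cohort(dir)
  expect_equal(back$titers, co$titers, tolerance = 1e-12)
  expect_equal(back$exposures, co$exposures)
  expect_identical(unname(back$features$stool_ko),
                   unname(co$features$stool_ko))
  expect_equal(back$metabolites, co$metabolites, tolerance = 1e-12)
})

test_that("an empty cohort writes header-only files", {
  co <- generate_cohort(small_cohort_config(seed = 47, n_subjects = 0))
  dir <- withr::local_tempdir()
  manifest <- write_cohort(co, dir)
  expect_true(all(manifest$rows[manifest$file != "thresholds.tsv"] == 0))
  expect_identical(readLines(file.path(dir, "titers.tsv")),
                   "subject_id\tantigen\ttimepoint\tvalue\tunits")
})

test_that("a one-timepoint cohort respects the titer row bound", {
  cfg <- cohort_config(n_subjects = 10, assess_rate_1yr = 1,
                       assess_rate_2yr = 0, visit_ages = c(61),
                       n_kos = 5, n_genera = 5, n_otus = 5,
                       n_metabolites = 5, n_modules = 2,
                       stool_depth = 200, nasal_depth = 200, seed = 53)
  co <- generate_cohort(cfg)
  expect_lte(nrow(co$titers), 190)   # 10 subjects x 19 antigens
  expect_equal(unique(co$titers$timepoint), "1yr")
})
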