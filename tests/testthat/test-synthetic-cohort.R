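test_that("config validation guards sizes, probabilities and noise", {
  expect_s3_class(cohort_config(), "cohort_config")
  expect_error(cohort_config(n = 0), "positive integer")
  expect_error(cohort_config(prevalence = c(0.5, 0.5, 0.2, -0.2)), "sum to 1")
  expect_error(cohort_config(epsilon = 1.5), "epsilon")
  expect_error(cohort_config(bmi_range = c(12, 18.5, 25, 30, 25)), "increasing")
})

test_that("configs round-trip through JSON and YAML", {
  cfg <- cohort_config(n = 50, seed = 9, epsilon = 0.25)
  jpath <- withr::local_tempfile(fileext = ".json")
  write_cohort_config(cfg, jpath)
  expect_equal(read_cohort_config(jpath), cfg)

  ypath <- withr::local_tempfile(fileext = ".yaml")
  yaml::write_yaml(list(n = 50, seed = 9, epsilon = 0.25), ypath)
  ycfg <- read_cohort_config(ypath)
  expect_equal(ycfg$n, 50L)
  expect_equal(ycfg$epsilon, 0.25)

  bad <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(list(n = 10, frobnicate = 1), bad, auto_unbox = TRUE)
  expect_error(read_cohort_config(bad), "unknown config field")
})

test_that("generation is deterministic and every record screens positive", {
  cfg <- cohort_config(n = 300, seed = 42)
  tab <- default_rule_table()
  a <- generate_cohort(cfg, tab)
  b <- generate_cohort(cfg, tab)
  expect_identical(a, b)

  # byte-identical CSV under identical (config, table)
  p1 <- withr::local_tempfile(fileext = ".csv")
  p2 <- withr::local_tempfile(fileext = ".csv")
  write_patient_csv(a, p1)
  write_patient_csv(b, p2)
  expect_identical(readLines(p1), readLines(p2))

  score <- rowSums(a[, paste0("scoff_", scoff_items())])
  expect_true(all(score >= 2))
  expect_true(all(a$age >= 18))
  expect_true(all(a$bmi > 0))
  expect_equal(anyDuplicated(a$id), 0)
  # a different seed gives a different cohort
  expect_false(identical(generate_cohort(cohort_config(n = 300, seed = 43), tab), a))
})

test_that("drawn BMI values stay inside their sampled class for both samplers", {
  tab <- default_rule_table()
  for (sampler in c("uniform", "normal")) {
    cfg <- cohort_config(n = 400, seed = 5, bmi_sampler = sampler)
    records <- generate_cohort(cfg, tab)
    out <- classify_cohort(records, tab)
    # the physician category distribution drives the class distribution:
    # hyperphagic records are overwhelmingly obese, restrictive underweight
    hd_cls <- out$bmi_class[out$true_category == "HD"]
    expect_gt(mean(hd_cls == "obese"), 0.8)
    rd_cls <- out$bmi_class[out$true_category == "RD"]
    expect_gt(mean(rd_cls == "underweight"), 0.6)
  }
})

test_that("zero noise on compatible classes yields perfect agreement", {
  tab <- default_rule_table()
  cfg <- compatible_config(cohort_config(n = 400, seed = 17, epsilon = 0))
  records <- generate_cohort(cfg, tab)
  cm <- build_confusion(records, tab)
  expect_equal(sum(diag(cm)), sum(cm))
  expect_equal(cohen_kappa(cm)$kappa, 1)
  # algorithm output equals the generating truth record-by-record
  out <- classify_cohort(records, tab)
  expect_identical(out$expali_category, records$true_category)
})

test_that("compatible_config zeroes structurally impossible classes", {
  cfg <- compatible_config(cohort_config())
  probs <- cfg$bmi_class_probs
  # no bulimic/hyperphagic/other cell exists in the underweight class
  expect_equal(probs[2, 1], 0)
  expect_equal(probs[3, 1], 0)
  expect_equal(probs[4, 1], 0)
  # no restrictive cell exists in overweight or obese classes
  expect_equal(probs[1, 3], 0)
  expect_equal(probs[1, 4], 0)
  expect_equal(unname(rowSums(probs)), rep(1, 4))
})

test_that("empirical BMI-class frequencies follow the configured distribution", {
  tab <- default_rule_table()
  cfg <- cohort_config(n = 10000, seed = 23)
  records <- generate_cohort(cfg, tab)
  cls <- table(factor(as.character(classify_bmi(records$bmi)), levels = bmi_classes()))
  # marginal class distribution implied by prevalence x class probs
  expected <- as.numeric(cfg$prevalence %*% cfg$bmi_class_probs)
  gof <- stats::chisq.test(as.integer(cls), p = expected)
  expect_gt(gof$p.value, 0.001)
})

test_that("agreement degrades monotonically with response noise", {
  tab <- default_rule_table()
  kappas <- vapply(c(0, 0.25, 0.6), function(eps) {
    cfg <- cohort_config(n = 2000, seed = 99, epsilon = eps)
    cohen_kappa(build_confusion(generate_cohort(cfg, tab), tab))$kappa
  }, numeric(1))
  expect_true(all(diff(kappas) < 0))
})

test_that("the recovery harness is deterministic and matches analytic sensitivity", {
  tab <- default_rule_table()
  cfg <- compatible_config(cohort_config(n = 150, seed = 3, epsilon = 0))
  s1 <- recover_operating_characteristics(cfg, tab, reps = 5)
  s2 <- recover_operating_characteristics(cfg, tab, reps = 5)
  expect_identical(s1, s2)
  expect_equal(s1$kappa_mean, 1)
  expect_equal(s1$kappa_sd, 0)
  expect_true(all(s1$per_category$sens_mean == 1))

  # analytic oracle for RD sensitivity under noise, by enumeration over the
  # BMI classes: within a class with m compatible (RD) cells out of 26, a
  # non-noisy draw returns RD with probability 1 if m > 0 (else m/26 = 0 via
  # the uniform fallback), and a noisy draw samples the 26 - m other cells
  # (falling back to all 26 when m = 26, as in the all-RD underweight class)
  eps <- 0.2
  cfg2 <- cohort_config(n = 4000, seed = 31, epsilon = eps)
  tab_df <- as.data.frame(tab)
  p_rd_given_class <- vapply(bmi_classes(), function(cls) {
    m <- sum(tab_df$category[tab_df$bmi_class == cls] == "RD")
    p_clean <- if (m > 0) 1 else m / 26
    p_noisy <- if (m < 26) 0 / (26 - m) else 1 # complement holds no RD cells
    (1 - eps) * p_clean + eps * p_noisy
  }, numeric(1))
  expected_sens <- sum(cfg2$bmi_class_probs[1, ] * p_rd_given_class)
  rec <- recover_operating_characteristics(cfg2, tab, reps = 8)
  n_rd <- 4000 * cfg2$prevalence[1]
  mc_sd <- sqrt(expected_sens * (1 - expected_sens) / n_rd) / sqrt(8)
  expect_lt(abs(rec$per_category$sens_mean[1] - expected_sens), 3 * mc_sd + 1e-6)
})
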