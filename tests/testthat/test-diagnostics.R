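# Exact operating characteristics of the embedded validation counts,
# frozen from direct fraction arithmetic (oracle: tp / row total etc.).
ref_fractions <- list(
  sens = c(RD = 50 / 65, BD = 27 / 39, HD = 67 / 84, OED = 3 / 18),
  spec = c(RD = 136 / 141, BD = 146 / 167, HD = 107 / 122, OED = 170 / 188)
)

test_that("confusion construction checks shape, counts and emptiness", {
  cm <- reference_confusion()
  expect_equal(sum(cm), 206)
  expect_equal(unname(rowSums(cm)), c(65, 39, 84, 18))
  expect_equal(unname(colSums(cm)), c(55, 48, 82, 21))
  expect_error(confusion_matrix(matrix(0, 4, 4)), "empty")
  expect_error(confusion_matrix(matrix(1, 3, 3)), "4x4")
  expect_error(confusion_matrix(matrix(-1, 4, 4)), "nonnegative")
})

test_that("build_confusion tallies physician vs algorithm and rejects bad cohorts", {
  tab <- default_rule_table()
  cohort <- make_tallied_cohort(unclass(reference_confusion()))
  cm <- build_confusion(cohort, tab)
  expect_equal(unclass(cm), unclass(reference_confusion()))

  one <- make_tallied_cohort(diag(c(1, 0, 0, 0)))
  cm1 <- build_confusion(one, tab)
  expect_equal(sum(cm1), 1)
  expect_equal(cm1["RD", "RD"], 1L)

  expect_error(build_confusion(cohort[0, ], tab), "non-empty")
  undx <- cohort
  undx$dsm5_diagnosis[2] <- ""
  expect_error(build_confusion(undx, tab), undx$id[2])
  neg <- cohort
  neg[1, c("scoff_control", "scoff_one_stone", "scoff_fat")] <- 0
  expect_error(build_confusion(neg, tab), "screen-negative")
})

test_that("sensitivity and specificity reproduce the validation fractions", {
  cm <- reference_confusion()
  for (cat in broad_categories()) {
    expect_equal(sensitivity(cm, cat)$estimate, ref_fractions$sens[[cat]])
    expect_equal(specificity(cm, cat)$estimate, ref_fractions$spec[[cat]])
    expect_equal(youden(cm, cat),
                 ref_fractions$sens[[cat]] + ref_fractions$spec[[cat]] - 1)
  }
  # a perfect classifier has sensitivity, specificity and Youden of 1
  perfect <- confusion_matrix(diag(c(10, 20, 30, 40)))
  for (cat in broad_categories()) {
    expect_equal(sensitivity(perfect, cat)$estimate, 1)
    expect_equal(specificity(perfect, cat)$estimate, 1)
    expect_equal(youden(perfect, cat), 1)
  }
  # undefined when no truth row exists
  norow <- confusion_matrix(rbind(c(0, 0, 0, 0), c(0, 5, 0, 0),
                                  c(0, 0, 5, 0), c(0, 0, 0, 5)))
  expect_error(sensitivity(norow, "RD"), "undefined sensitivity")
})

test_that("Youden is zero when the assignment is independent of the truth", {
  # columns proportional to fixed weights in every row: FPR equals TPR
  weights <- c(2, 3, 4, 1)
  rows <- c(10, 20, 40, 30)
  cm <- confusion_matrix(outer(rows, weights))
  for (cat in broad_categories()) {
    expect_equal(youden(cm, cat), 0, tolerance = 1e-12)
  }
  # and Youden is invariant to scaling all counts
  cm5 <- confusion_matrix(unclass(reference_confusion()) * 5L)
  for (cat in broad_categories()) {
    expect_equal(youden(cm5, cat), youden(reference_confusion(), cat))
  }
})

test_that("continuity-corrected Wald intervals match hand-computed bounds and truncate", {
  ci <- wald_cc_ci(50, 65)
  # oracle: p +- (1.959964 * sqrt(p(1-p)/n) + 1/(2n)) computed directly
  p <- 50 / 65
  half <- qnorm(0.975) * sqrt(p * (1 - p) / 65) + 1 / 130
  expect_equal(ci$lower, p - half)
  expect_equal(ci$upper, p + half)
  expect_equal(round(100 * ci$lower, 1), 65.9)
  expect_equal(round(100 * ci$upper, 1), 87.9)

  lo0 <- wald_cc_ci(3, 18)
  expect_equal(lo0$lower, 0) # truncated at 0
  expect_equal(round(100 * lo0$upper, 1), 36.7)
  expect_equal(wald_cc_ci(10, 10)$upper, 1) # truncated at 1
  expect_equal(wald_cc_ci(0, 10)$lower, 0)

  expect_error(wald_cc_ci(11, 10), "successes")
  expect_error(wald_cc_ci(-1, 10), "successes")
  expect_error(wald_cc_ci(5, 10, level = 1.2), "level")
})

test_that("alternative CI methods agree with their standard references", {
  # Wilson vs stats::prop.test without continuity correction
  for (case in list(c(50, 65), c(3, 18), c(107, 122))) {
    w <- wald_cc_ci(case[1], case[2], method = "wilson")
    ref <- stats::prop.test(case[1], case[2], correct = FALSE)$conf.int
    expect_equal(c(w$lower, w$upper), as.numeric(ref), tolerance = 1e-10)
  }
  # all methods keep bounds in [0,1] ordered around the estimate
  for (m in c("wald-cc", "wald", "wilson", "clopper-pearson")) {
    for (case in list(c(0, 5), c(5, 5), c(1, 50), c(49, 50))) {
      ci <- wald_cc_ci(case[1], case[2], method = m)
      expect_true(ci$lower >= 0 && ci$upper <= 1)
      expect_true(ci$lower <= ci$estimate && ci$estimate <= ci$upper)
    }
  }
})

test_that("Cohen's kappa matches the closed form and its boundary cases", {
  k <- cohen_kappa(reference_confusion())
  # oracle: po and pe as exact fractions of the embedded counts
  po <- 147 / 206
  pe <- 12713 / 42436
  expect_equal(k$po, po)
  expect_equal(k$pe, pe)
  expect_equal(k$kappa, (po - pe) / (1 - pe))
  expect_equal(round(k$kappa, 2), 0.59)
  expect_equal(k$se, sqrt(po * (1 - po) / (206 * (1 - pe)^2)))
  expect_true(k$lower < k$kappa && k$kappa < k$upper)

  expect_equal(cohen_kappa(confusion_matrix(diag(c(5, 6, 7, 8))))$kappa, 1)
  indep <- confusion_matrix(outer(c(10, 20, 40, 30), c(2, 3, 4, 1)))
  expect_equal(cohen_kappa(indep)$kappa, 0, tolerance = 1e-12)
  expect_true(cohen_kappa(reference_confusion())$kappa <= po)
})

test_that("kappa agrees with the independent e1071 implementation on random tables", {
  withr::local_seed(7)
  for (i in 1:25) {
    m <- matrix(rpois(16, 8) + 1L, 4, 4)
    ours <- cohen_kappa(confusion_matrix(m))$kappa
    theirs <- e1071::classAgreement(m)$kappa
    expect_equal(ours, theirs, tolerance = 1e-12)
  }
})

test_that("one-vs-rest counts satisfy the TN identity on random matrices", {
  withr::local_seed(11)
  for (i in 1:20) {
    cm <- confusion_matrix(matrix(rpois(16, 6), 4, 4) + diag(4L))
    n <- sum(cm)
    tps <- 0
    report <- evaluate_all(cm)
    for (j in 1:4) {
      row <- report$metrics[j, ]
      expect_equal(row$tp + row$fn + row$fp + row$tn, n)
      expect_equal(row$tp + row$fn, sum(cm[j, ]))
      expect_equal(row$tp + row$fp, sum(cm[, j]))
      tps <- tps + row$tp
    }
    expect_equal(tps, sum(diag(cm)))
  }
})

test_that("evaluate_all renders the published layout and writes CSV", {
  report <- evaluate_all(reference_confusion())
  expect_equal(round(report$metrics$youden, 2), c(0.73, 0.57, 0.67, 0.07))
  expect_equal(report$metrics$tp, c(50, 27, 67, 3))
  txt <- capture.output(print(report))
  expect_true(any(grepl("27/39-69.2%", txt, fixed = TRUE)))
  expect_true(any(grepl("(65.9-87.9)", txt, fixed = TRUE)))

  path <- withr::local_tempfile(fileext = ".csv")
  write_metrics_csv(report, path)
  back <- utils::read.csv(path)
  expect_equal(back$category, c(broad_categories(), "kappa"))
  expect_equal(back$sensitivity[1:4], report$metrics$sensitivity)

  perfect <- evaluate_all(confusion_matrix(diag(c(5, 5, 5, 5))))
  expect_true(all(perfect$metrics$sensitivity == 1))
  expect_true(all(perfect$metrics$specificity == 1))
  expect_equal(perfect$kappa$kappa, 1)
})

test_that("confusion matrices round-trip through labelled CSV", {
  path <- withr::local_tempfile(fileext = ".csv")
  write_confusion_csv(reference_confusion(), path)
  back <- read_confusion_csv(path)
  expect_equal(unclass(back), unclass(reference_confusion()))
})
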