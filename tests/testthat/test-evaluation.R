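test_that("confusion matrices count and normalise correctly", {
  cm <- confusion_matrix(c("A", "A", "B"), c("A", "B", "B"),
                         classes = c("A", "B"))
  expect_equal(unclass(cm), matrix(c(1, 0, 1, 1), 2,
                                   dimnames = list(true = c("A", "B"),
                                                   predicted = c("A", "B"))),
               ignore_attr = "class")
  expect_equal(sum(cm), 3)   # conservation: entries sum to evaluated ticks

  cmn <- confusion_matrix(c("A", "A", "B"), c("A", "B", "B"),
                          classes = c("A", "B"), normalize = TRUE)
  expect_equal(unname(rowSums(cmn)), c(1, 1))

  perfect <- confusion_matrix(rep(c("A", "B"), 5), rep(c("A", "B"), 5))
  expect_true(all(perfect[row(perfect) != col(perfect)] == 0))

  expect_error(confusion_matrix("A", c("A", "B")), "length")
  expect_error(confusion_matrix("Z", "A", classes = "A"), "outside")
})

test_that("per-class metrics match hand arithmetic and a definition loop", {
  # TP=8, FP=2, FN=2, TN=88
  cm <- matrix(c(8, 2, 2, 88), 2, byrow = TRUE,
               dimnames = list(true = c("P", "N"), predicted = c("P", "N")))
  met <- class_metrics(cm)
  expect_equal(met$f1[1], 80)
  expect_equal(met$accuracy[1], 96)
  expect_equal(met$misclassification[1], 20)

  perfect <- confusion_matrix(rep(c("A", "B"), 10), rep(c("A", "B"), 10))
  mp <- class_metrics(perfect)
  expect_true(all(mp$f1 == 100 & mp$accuracy == 100 &
                    mp$misclassification == 0))

  # random matrices against an independently coded definition loop
  set.seed(61)
  for (trial in 1:20) {
    k <- sample(2:5, 1)
    cmr <- matrix(rpois(k * k, 8) + 1, k,
                  dimnames = list(true = paste0("c", 1:k),
                                  predicted = paste0("c", 1:k)))
    met <- class_metrics(cmr)
    N <- sum(cmr)
    for (c_ in 1:k) {
      TP <- cmr[c_, c_]; FP <- sum(cmr[, c_]) - TP; FN <- sum(cmr[c_, ]) - TP
      P <- TP / (TP + FP); R <- TP / (TP + FN)
      expect_equal(met$f1[c_], 100 * 2 * P * R / (P + R), tolerance = 1e-12)
      expect_equal(met$accuracy[c_], 100 * (N - FP - FN) / N,
                   tolerance = 1e-12)
      expect_equal(met$misclassification[c_], 100 * (1 - R),
                   tolerance = 1e-12)
    }
  }
})

test_that("macro-F1 is invariant under class relabeling", {
  set.seed(71)
  truth <- sample(c("a", "b", "c"), 300, replace = TRUE)
  pred <- ifelse(runif(300) < 0.8, truth,
                 sample(c("a", "b", "c"), 300, replace = TRUE))
  f1 <- macro_f1(truth, pred, c("a", "b", "c"))
  perm <- c(a = "z", b = "x", c = "y")
  expect_equal(macro_f1(unname(perm[truth]), unname(perm[pred]),
                        c("x", "y", "z")), f1, tolerance = 1e-12)
})

test_that("Wilcoxon comparison handles ties, zeros and exact small n", {
  same <- wilcoxon_compare(1:10, 1:10)
  expect_equal(same$p_value, 1)
  expect_false(same$significant)
  expect_equal(same$n_effective, 0)

  # n = 6, all differences positive: exact two-sided p = 2/64
  w <- wilcoxon_compare(c(11, 12, 13, 14, 15, 16), c(10, 10, 10, 10, 10, 10))
  expect_equal(w$p_value, 2 / 64)
  expect_true(w$significant)

  expect_error(wilcoxon_compare(1:3, 1:4), "length")
})

test_that("Wilcoxon p agrees with full sign-assignment enumeration", {
  set.seed(81)
  for (trial in 1:20) {
    n <- sample(6:12, 1)
    a <- rnorm(n)
    b <- rnorm(n)
    w <- wilcoxon_compare(a, b)
    expect_equal(w$p_value, wilcoxon_enum_p(a - b), tolerance = 1e-8)
  }
})

test_that("small experiments run end to end, deterministically", {
  cfg <- experiment_config(n_subjects = 2, seed = 5,
                           protocol = session_protocol(rate_hz = 100),
                           nlr_grid = data.frame(degree = 1, TH = 0.5),
                           nlr_max_iter = 100)
  rep1 <- run_experiment(cfg)
  expect_s3_class(rep1, "eval_report")
  expect_length(rep1$subjects, 2)
  expect_named(rep1$aggregate, c("gesture", "spherical_force", "tip_force"))
  for (cl in names(rep1$aggregate)) {
    expect_true(is.finite(rep1$aggregate[[cl]]$nlr$mean_macro_f1))
    expect_true(is.finite(rep1$aggregate[[cl]]$lda$mean_macro_f1))
    expect_true(rep1$wilcoxon[[cl]]$p_value >= 0 &&
                  rep1$wilcoxon[[cl]]$p_value <= 1)
  }
  expect_true(validate_report(rep1))

  # byte-identical report JSON for identical config + seed
  rep2 <- run_experiment(cfg)
  f1 <- withr::local_tempfile(fileext = ".json")
  f2 <- withr::local_tempfile(fileext = ".json")
  write_report_json(rep1, f1)
  write_report_json(rep2, f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
})

test_that("report validation flags structural damage", {
  cfg <- experiment_config(n_subjects = 2, seed = 6,
                           protocol = session_protocol(rate_hz = 100),
                           nlr_grid = data.frame(degree = 1, TH = 0.5),
                           nlr_max_iter = 50)
  rep <- run_experiment(cfg)
  plain <- semghier:::.report_to_plain(rep)
  plain$wilcoxon$gesture$p_value <- NULL
  expect_error(validate_report(plain), "schema validation")
})
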