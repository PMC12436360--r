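# Statistical engine: AUROC, Youden, exact CIs, DeLong, McNemar.

test_that("auroc handles separation, ties and the 3-of-4-pairs case", {
  expect_equal(auroc(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0)), 1)
  expect_equal(auroc(rep(0.5, 6), c(1, 1, 1, 0, 0, 0)), 0.5)
  expect_equal(auroc(c(0.9, 0.4, 0.7, 0.3), c(1, 1, 0, 0)), 0.75)
  expect_error(auroc(1:3, c(1, 1, 1)), "both classes")
})

test_that("auroc equals the trapezoidal ROC area and pROC on random instances", {
  skip_if_not_installed("pROC")
  withr::with_seed(11, {
    for (i in 1:200) {
      n <- sample(8:40, 1)
      labels <- c(1, 0, sample(0:1, n - 2, replace = TRUE))
      scores <- round(runif(n), sample(c(1, 2, 6), 1))  # force ties sometimes
      a <- auroc(scores, labels)
      expect_equal(a, trapezoidAuroc(scores, labels), tolerance = 1e-12)
      if (i <= 25) {
        pr <- suppressMessages(pROC::auc(labels, scores,
                                         direction = "<", quiet = TRUE))
        expect_equal(a, as.numeric(pr), tolerance = 1e-12)
      }
    }
  })
})

test_that("youden cutoff maximizes J with ties broken toward sensitivity", {
  yc <- youdenCutoff(c(0.9, 0.8, 0.4, 0.7, 0.3, 0.2), c(1, 1, 1, 0, 0, 0))
  expect_equal(yc$threshold, 0.4)
  expect_equal(yc$J, 2 / 3)
  expect_equal(youdenCutoff(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0))$J, 1)
  expect_equal(youdenCutoff(rep(0.3, 4), c(1, 1, 0, 0))$J, 0)
  withr::with_seed(13, {
    for (i in 1:50) {
      n <- sample(6:50, 1)
      labels <- c(1, 0, sample(0:1, n - 2, replace = TRUE))
      scores <- round(runif(n), 2)
      got <- youdenCutoff(scores, labels)
      ora <- youdenOracle(scores, labels)
      expect_equal(got$J, ora$J, tolerance = 1e-12)
      expect_equal(got$threshold, ora$thr)
    }
  })
})

test_that("exact binomial CI matches binom.test and the boundary conventions", {
  for (kn in list(c(13, 31), c(0, 10), c(10, 10), c(5, 50), c(89, 110))) {
    got <- clopperPearsonCi(kn[1], kn[2])
    ref <- binom.test(kn[1], kn[2])$conf.int
    expect_equal(got, as.numeric(ref), tolerance = 1e-10)
  }
  expect_identical(clopperPearsonCi(0, 10)[1], 0)
  expect_identical(clopperPearsonCi(10, 10)[2], 1)
  expect_error(clopperPearsonCi(5, 4), "k <= n")
})

test_that("exact binomial coverage at n = 31, p = 0.42 is at least 94%", {
  withr::with_seed(17, {
    k <- rbinom(2000, 31, 0.42)
    cover <- vapply(k, function(ki) {
      ci <- clopperPearsonCi(ki, 31)
      ci[1] <= 0.42 && 0.42 <= ci[2]
    }, logical(1))
    expect_gte(mean(cover), 0.94)
  })
})

test_that("confusion metrics reproduce hand arithmetic and flag undefined ratios", {
  m <- metricsFromConfusion(new("ConfusionCounts", tp = 13L, fp = 21L,
                                fn = 18L, tn = 89L))
  get <- function(name) m$value[m$metric == name]
  expect_equal(round(100 * get("sensitivity"), 1), 41.9)
  expect_equal(round(100 * get("specificity"), 1), 80.9)
  expect_equal(round(100 * get("ppv"), 1), 38.2)
  expect_equal(round(100 * get("npv"), 1), 83.2)
  expect_equal(get("f1"), f1Score(get("sensitivity"), get("ppv")))
  d <- metricsFromConfusion(new("ConfusionCounts", tp = 0L, fp = 3L,
                                fn = 0L, tn = 7L))
  expect_true(is.na(d$value[d$metric == "sensitivity"]))
  expect_match(d$note[d$metric == "sensitivity"], "tp \\+ fn")
  expect_equal(d$value[d$metric == "specificity"], 0.7)
  expect_error(metricsFromConfusion(new("ConfusionCounts", tp = 0L, fp = 0L,
                                        fn = 0L, tn = 0L)))
})

test_that("f1 is the harmonic mean of sensitivity and PPV", {
  expect_equal(f1Score(0.658, 0.709), 2 * 0.658 * 0.709 / (0.658 + 0.709))
  expect_true(is.na(f1Score(0, 0)))
})

test_that("DeLong test is internally consistent and matches pROC", {
  withr::with_seed(23, {
    labels <- c(rep(1, 12), rep(0, 18))
    sa <- rnorm(30) + labels
    sb <- 0.6 * sa + rnorm(30)
    dl <- delongTest(sa, sb, labels)
    expect_equal(dl$aucA, auroc(sa, labels), tolerance = 1e-12)
    expect_equal(dl$aucB, auroc(sb, labels), tolerance = 1e-12)
    same <- delongTest(sa, sa, labels)
    expect_equal(same$diff, 0)
    expect_equal(same$p, 1)
    skip_if_not_installed("pROC")
    pr <- suppressMessages(pROC::roc.test(
      pROC::roc(labels, sa, direction = "<", quiet = TRUE),
      pROC::roc(labels, sb, direction = "<", quiet = TRUE),
      method = "delong"))
    expect_equal(dl$p, as.numeric(pr$p.value), tolerance = 1e-8)
  })
  expect_error(delongTest(1:3, 1:4, c(1, 0, 1)), "equal length")
})

test_that("McNemar exact/chi-square conventions hold", {
  expect_equal(mcnemarTest(5, 5), 1)
  expect_equal(mcnemarTest(10, 2), 158 / 4096)
  expect_equal(mcnemarTest(0, 0), 1)
  # large-sample branch agrees with the continuity-corrected chi-square
  ref <- mcnemar.test(matrix(c(10, 30, 12, 10), 2, 2), correct = TRUE)
  expect_equal(mcnemarTest(30, 12), as.numeric(ref$p.value), tolerance = 1e-12)
  expect_error(mcnemarTest(-1, 2), "non-negative")
})

test_that("five-point scores dichotomize at probable fracture", {
  expect_equal(dichotomizeScores(c(1, 2, 3, 4, 5)), c(0L, 0L, 0L, 1L, 1L))
  expect_error(dichotomizeScores(c(2, 6)), "1..5")
})

test_that("model report evaluates at the Youden point and records the threshold source", {
  withr::with_seed(31, {
    labels <- c(rep(1, 15), rep(0, 35))
    scores <- runif(50) + 0.6 * labels
    rep1 <- modelReport(scores, labels)
    expect_equal(rep1$thresholdSource, "youden_on_these_scores")
    expect_equal(rep1$threshold, youdenCutoff(scores, labels)$threshold)
    rep2 <- modelReport(scores, labels, threshold = 0.8)
    expect_equal(rep2$thresholdSource, "supplied")
    cc <- rep2$counts
    expect_equal(cc@tp + cc@fp + cc@fn + cc@tn, 50L)
  })
})
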