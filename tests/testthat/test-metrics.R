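test_that("one-vs-rest AUCs equal the pair-counting oracle on a worked 3-class fixture", {
  sch <- grading_scheme(1)
  y <- c(0, 0, 0, 0, 1, 1, 1, 1, 2, 2, 2, 0)
  prob <- rbind(
    c(.7, .2, .1), c(.6, .3, .1), c(.5, .3, .2), c(.3, .4, .3),
    c(.2, .6, .2), c(.3, .5, .2), c(.4, .4, .2), c(.1, .7, .2),
    c(.1, .2, .7), c(.2, .3, .5), c(.3, .3, .4), c(.5, .25, .25))
  rep <- compute_report(y, prob, sch)
  for (k in 0:2)
    expect_equal(rep$per_class[[k + 1]]$auc,
                 oracle_auc(as.integer(y == k), prob[, k + 1]),
                 tolerance = 1e-12)
  expect_equal(rep$macro_auc,
               mean(sapply(0:2, function(k)
                 oracle_auc(as.integer(y == k), prob[, k + 1]))),
               tolerance = 1e-12)
  expect_equal(rep$accuracy,
               mean(max.col(prob, ties.method = "first") - 1 == y))
})

test_that("report metrics match brute-force oracles on random fixtures", {
  withr::with_seed(42, {
    for (rep_i in 1:60) {
      K <- sample(c(3, 4), 1)
      sch <- grading_scheme(if (K == 3) 1 else 3)
      n <- sample(15:40, 1)
      y <- sample(0:(K - 1), n, TRUE)
      if (length(unique(y)) < K) y[1:K] <- 0:(K - 1)  # keep AUC defined
      prob <- random_prob_matrix(n, K)
      r <- compute_report(y, prob, sch)
      pred <- max.col(prob, ties.method = "first") - 1
      aucs <- sapply(1:K, function(k)
        oracle_auc(as.integer(y == k - 1), prob[, k]))
      expect_equal(r$macro_auc, mean(aucs), tolerance = 1e-10)
      for (k in 1:K) {
        oc <- oracle_cui(y, pred, k - 1)
        if (!is.na(r$per_class[[k]]$cui_plus))
          expect_equal(r$per_class[[k]]$cui_plus, oc$cui_plus,
                       tolerance = 1e-10)
        if (!is.na(r$per_class[[k]]$cui_minus))
          expect_equal(r$per_class[[k]]$cui_minus, oc$cui_minus,
                       tolerance = 1e-10)
      }
      expect_equal(r$qwk, oracle_qwk(y, pred, K), tolerance = 1e-10)
    }
  })
})

test_that("label-independent scores give chance-level macro-AUC", {
  withr::with_seed(7, {
    y <- sample(0:2, 2000, TRUE, prob = c(.5, .3, .2))
    prob <- random_prob_matrix(2000, 3)
  })
  r <- compute_report(y, prob, grading_scheme(1))
  expect_equal(r$macro_auc, 0.5, tolerance = 0.03)
})

test_that("clinical utility index computes and bands correctly", {
  # hand-computed example: cm [[45,5],[10,40]], positive class = first
  cm <- matrix(c(45, 5, 10, 40), 2, byrow = TRUE)
  r <- cui(cm, 1)
  expect_equal(r$cui_plus, (45 / 50) * (45 / 55), tolerance = 1e-12)
  expect_equal(r$band_plus, "good")
  expect_equal(cui_band(0.700), "good")
  expect_equal(cui_band(0.81), "excellent")
  expect_equal(cui_band(0.489), "poor")
  expect_equal(cui_band(0.49), "satisfactory")
  # perfect classifier
  p <- cui(matrix(c(30, 0, 0, 70), 2, byrow = TRUE), 1)
  expect_equal(p$cui_plus, 1)
  expect_equal(p$band_plus, "excellent")
  # degenerate: class never predicted nor present -> undefined, no error
  u <- cui(matrix(c(0, 0, 0, 50), 2, byrow = TRUE), 1)
  expect_true(is.na(u$cui_plus))
  expect_equal(u$band_plus, "undefined")
  # CUI+ never exceeds min(sensitivity, PPV)
  withr::with_seed(3, for (i in 1:50) {
    cm <- matrix(rpois(4, 20), 2)
    o <- milgrade:::ovr_counts(cm, 1)
    r <- cui(cm, 1)
    if (!is.na(r$cui_plus))
      expect_lte(r$cui_plus,
                 min(o$tp / (o$tp + o$fn), o$tp / (o$tp + o$fp)) + 1e-12)
  })
})

test_that("quadratic weighted kappa matches its direct-formula oracle", {
  expect_equal(quadratic_weighted_kappa(c(0, 1, 2, 3), c(0, 1, 2, 3), 4), 1)
  r1 <- c(0, 1, 2, 3); r2 <- c(3, 2, 1, 0)
  expect_equal(quadratic_weighted_kappa(r1, r2, 4),
               oracle_qwk(r1, r2, 4), tolerance = 1e-12)
  withr::with_seed(9, for (i in 1:40) {
    K <- sample(3:4, 1); n <- sample(10:60, 1)
    a <- sample(0:(K - 1), n, TRUE); b <- sample(0:(K - 1), n, TRUE)
    k <- quadratic_weighted_kappa(a, b, K)
    expect_equal(k, oracle_qwk(a, b, K), tolerance = 1e-10)
    expect_gte(k, -1); expect_lte(k, 1)
  })
  # one rater constant, the other uniform: kappa -> 0
  withr::with_seed(10, {
    a <- rep(1, 4000); b <- sample(0:3, 4000, TRUE)
    expect_equal(quadratic_weighted_kappa(a, b, 4), 0, tolerance = 0.05)
  })
  expect_error(quadratic_weighted_kappa(1:3, 1:2, 4), "invalid input")
})

test_that("McNemar's test agrees with symmetric, exact and corrected oracles", {
  sym <- mcnemar_test(20, 20, correction = FALSE, method = "chisq")
  expect_equal(sym$statistic, 0)
  expect_equal(sym$p_value, 1)
  # exact two-sided binomial tail oracle for small discordance
  ex <- mcnemar_test(10, 2)
  expect_equal(ex$method, "exact")
  expect_equal(ex$p_value, 2 * pbinom(2, 12, 0.5), tolerance = 1e-12)
  # continuity correction always increases p
  withr::with_seed(11, for (i in 1:40) {
    n01 <- sample(5:60, 1); n10 <- sample(5:60, 1)
    p0 <- mcnemar_test(n01, n10, correction = FALSE, method = "chisq")$p_value
    p1 <- mcnemar_test(n01, n10, correction = TRUE, method = "chisq")$p_value
    expect_gte(p1, p0 - 1e-12)
  })
  # exact and chi-squared agree for large discordant totals
  withr::with_seed(12, for (i in 1:20) {
    n01 <- sample(20:60, 1); n10 <- sample(20:60, 1)
    if (n01 + n10 < 50) next
    pe <- mcnemar_test(n01, n10, method = "exact")$p_value
    pc <- mcnemar_test(n01, n10, method = "chisq")$p_value
    expect_lt(abs(pe - pc), 0.02)
  })
  und <- mcnemar_test(0, 0)
  expect_true(und$undefined)
})

test_that("DeLong's test returns pair-counting AUCs and honest p-values", {
  withr::with_seed(13, {
    y <- rep(0:1, each = 40)
    s1 <- rnorm(80) + y
    s2 <- rnorm(80) + 0.3 * y
  })
  r <- delong_test(y, s1, s2)
  expect_equal(r$auc1, oracle_auc(y, s1), tolerance = 1e-12)
  expect_equal(r$auc2, oracle_auc(y, s2), tolerance = 1e-12)
  expect_true(r$p_value >= 0 && r$p_value <= 1)
  same <- delong_test(y, s1, s1)
  expect_equal(same$z, 0)
  expect_equal(same$p_value, 1)
  expect_error(delong_test(rep(1, 10), rnorm(10), rnorm(10)),
               "invalid input")
  # a known signal gap is detected in most seeded replicates
  hits <- 0
  withr::with_seed(14, for (i in 1:30) {
    y <- rep(0:1, each = 100)
    s1 <- rnorm(200) + 1.2 * y
    s2 <- rnorm(200) + 0.2 * y
    if (delong_test(y, s1, s2)$p_value < 0.05) hits <- hits + 1
  })
  expect_gte(hits, 27)
})

test_that("2x2 chi-squared matches the textbook formula, corrected and not", {
  withr::with_seed(15, for (i in 1:200) {
    tb <- matrix(sample(1:80, 4, TRUE), 2)
    for (yates in c(TRUE, FALSE)) {
      r <- chi2_2x2(tb, yates = yates)
      expect_equal(r$statistic,
                   oracle_chi2(tb[1, 1], tb[1, 2], tb[2, 1], tb[2, 2],
                               yates),
                   tolerance = 1e-10)
    }
  })
  ident <- chi2_2x2(matrix(c(30, 20, 30, 20), 2, byrow = TRUE))
  expect_equal(ident$statistic, 0)
  expect_equal(ident$p_value, 1)
  expect_error(chi2_2x2(matrix(c(0, 0, 5, 5), 2)), "invalid input")
})

test_that("reports flag undefined metrics instead of coercing them", {
  sch <- grading_scheme(3)
  y <- c(0, 0, 1, 1, 2, 2)   # severe absent
  prob <- random_prob_matrix(6, 4)
  expect_warning(r <- compute_report(y, prob, sch), "absent")
  expect_true(is.na(r$per_class[["severe"]]$auc))
  expect_false(is.na(r$macro_auc))
  expect_error(compute_report(y, prob[, 1:3], sch), "columns")
  expect_error(compute_report(y, prob * 2, sch), "sum to 1")
})
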