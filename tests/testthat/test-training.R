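test_that("rebalanced loss reduces to mean cross-entropy under uniform statistics", {
  K <- 4
  withr::with_seed(20, {
    logits <- matrix(rnorm(10 * K), 10)
    labels <- sample(0:(K - 1), 10, TRUE)
  })
  st <- loss_state(K)
  r <- rebalanced_loss(logits, labels, st)
  ce <- mean(vapply(1:10, function(i) {
    p <- exp(logits[i, ] - max(logits[i, ]))
    p <- p / sum(p)
    -log(p[labels[i] + 1])
  }, 0))
  expect_equal(r$loss, ce, tolerance = 1e-6)
  expect_equal(mean(r$weights), 1, tolerance = 1e-6)
  # nonuniform statistics break the equality
  st2 <- st; st2$stat <- c(2, 1, 0.5, 0.1)
  r2 <- rebalanced_loss(logits, labels, st2)
  expect_gt(max(abs(r2$weights - 1)), 0.01)
  expect_equal(mean(r2$weights), 1, tolerance = 1e-9)
  # single-class batch stays finite
  r3 <- rebalanced_loss(logits, rep(2L, 10), st)
  expect_true(is.finite(r3$loss))
  expect_true(all(is.finite(r3$weights)))
  expect_error(rebalanced_loss(logits[0, , drop = FALSE], integer(), st),
               "empty batch")
})

test_that("a long-tailed stream up-weights minority classes", {
  K <- 4
  priors <- c(0.66, 0.14, 0.12, 0.08)
  st <- loss_state(K)
  wsum <- numeric(K); wn <- numeric(K)
  withr::with_seed(21, {
    for (step in 1:50) {
      labels <- sample(0:(K - 1), 8, TRUE, prob = priors)
      logits <- matrix(rnorm(8 * K, sd = 0.5), 8)
      r <- rebalanced_loss(logits, labels, st)
      st <- r$state
      for (k in 0:(K - 1)) {
        wsum[k + 1] <- wsum[k + 1] + sum(r$weights[labels == k])
        wn[k + 1] <- wn[k + 1] + sum(labels == k)
      }
    }
  })
  wmean <- wsum / wn
  expect_gt(wmean[4], wmean[1])      # rarest above majority
  expect_gt(mean(wmean[3:4]), mean(wmean[1:2]))
  expect_true(all(st$stat >= 0))
  expect_equal(sum(st$count), 400)
})

test_that("stratified folds are disjoint, covering and balanced within one slide", {
  labels <- setNames(rep(0:3, c(40, 30, 20, 10)),
                     sprintf("s%03d", 1:100))
  plan <- make_folds(labels, k = 5, seed = 3)
  expect_setequal(plan$slide_id, names(labels))
  expect_equal(sort(unique(plan$fold)), 0:4)
  tab <- table(plan$label, plan$fold)
  for (k in 1:4) {
    expected <- c(8, 6, 4, 2)[k]
    expect_true(all(abs(tab[k, ] - expected) <= 1))
  }
  # reproducible; different seeds differ
  expect_identical(make_folds(labels, 5, seed = 3), plan)
  expect_false(identical(make_folds(labels, 5, seed = 4)$fold, plan$fold))
  expect_error(make_folds(labels, k = 1), "invalid input")
})

test_that("zero-epoch training returns the initialization; seeds reproduce loss curves", {
  sch <- grading_scheme(3)
  spec <- tiny_spec(priors = rep(0.25, 4))
  coh <- generate_cohort(spec, 24, seed = 5)
  cfg <- tiny_config(K = 4, D = 24, seed = 2)
  fit0 <- mil_grader(coh$bags, coh$labels$grade, sch, cfg,
                     train_config(epochs = 0))
  expect_equal(fit0$params, milgrade:::mil_init(cfg), tolerance = 1e-12)
  # predictions at initialization are unsaturated, near chance
  pr0 <- predict(fit0, coh$bags, type = "prob")
  expect_lt(max(abs(pr0 - 0.25)), 0.45)
  expect_lt(abs(mean(pr0) - 0.25), 1e-6)
  tr <- train_config(epochs = 3, seed = 9)
  fit1 <- mil_grader(coh$bags, coh$labels$grade, sch, cfg, tr)
  fit2 <- mil_grader(coh$bags, coh$labels$grade, sch, cfg, tr)
  expect_identical(fit1$loss_history, fit2$loss_history)
  expect_identical(fit1$params, fit2$params)
  expect_length(fit1$loss_history, 3)
})

test_that("cross-validation trains per fold and pools out-of-fold predictions", {
  sch <- grading_scheme(1)
  spec <- tiny_spec(K = 3, priors = c(0.4, 0.35, 0.25), separation = 4)
  coh <- generate_cohort(spec, 45, seed = 6)
  cfg <- tiny_config(K = 3, D = 24, seed = 1)
  cv <- mil_crossval(coh$bags, coh$labels$grade, sch, cfg,
                     train_config(epochs = 4, accum = 2, seed = 1),
                     k = 3, seed = 2)
  expect_s3_class(cv, "mil_cv")
  expect_equal(nrow(cv$oof), 45)
  expect_setequal(cv$oof$slide_id, coh$labels$slide_id)
  expect_length(cv$per_fold, 3)
  expect_true(cv$best_fold %in% 0:2)
  expect_s3_class(best_model(cv), "mil_grader")
  # every slide predicted exactly once out-of-fold
  expect_false(anyDuplicated(cv$oof$slide_id) > 0)
  # easy task at wide separation: CV recovers labels well above chance
  expect_gt(cv$report$macro_auc, 0.8)
})

test_that("fine-tuning resumes from the checkpoint and 0 epochs is a no-op", {
  sch <- grading_scheme(3)
  spec <- tiny_spec(priors = rep(0.25, 4))
  coh <- generate_cohort(spec, 30, seed = 8)
  cfg <- tiny_config(K = 4, D = 24, seed = 3)
  fit <- mil_grader(coh$bags, coh$labels$grade, sch, cfg,
                    train_config(epochs = 2, seed = 1))
  shifted <- generate_cohort(corpus_shift(spec, 0.5, seed = 9), 20,
                             seed = 10)
  ft0 <- fine_tune(fit, shifted$bags, shifted$labels$grade,
                   train = train_config(epochs = 0))
  expect_equal(predict(ft0, coh$bags[1:5], type = "prob"),
               predict(fit, coh$bags[1:5], type = "prob"),
               tolerance = 1e-12)
  ft <- fine_tune(fit, shifted$bags, shifted$labels$grade,
                  train = train_config(epochs = 2, seed = 2))
  expect_false(identical(ft$params$W1, fit$params$W1))
  # label outside the scheme is rejected
  expect_error(fine_tune(fit, shifted$bags,
                         rep(5L, length(shifted$bags))), "0..K-1")
})

test_that("checkpoints round-trip and refuse foreign payloads", {
  sch <- grading_scheme(2)
  spec <- tiny_spec(K = 3, priors = c(.6, .25, .15))
  coh <- generate_cohort(spec, 15, seed = 11)
  cfg <- tiny_config(K = 3, D = 24, seed = 4)
  fit <- mil_grader(coh$bags, coh$labels$grade, sch, cfg,
                    train_config(epochs = 1))
  f <- tempfile(fileext = ".rds")
  save_checkpoint(fit, f)
  back <- load_checkpoint(f)
  expect_equal(predict(back, coh$bags[1:3], type = "prob"),
               predict(fit, coh$bags[1:3], type = "prob"))
  saveRDS(list(x = 1), f)
  expect_error(load_checkpoint(f), "format error")
})
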