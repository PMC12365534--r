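cfg0 <- tiny_config(K = 4, D = 24, seed = 11)
par0 <- milgrade:::mil_init(cfg0)

test_that("embedding is a per-instance map", {
  X <- withr::with_seed(1, random_bag(6, 24))
  X[2, ] <- X[1, ]
  H <- mil_embed(X, cfg0, par0)
  expect_identical(H[1, ], H[2, ])
  expect_equal(dim(H), c(6, cfg0$embed_dim))
  expect_equal(dim(mil_embed(X[1, , drop = FALSE], cfg0, par0)),
               c(1, cfg0$embed_dim))
  i <- c(4, 2, 6, 1, 3, 5)
  expect_identical(mil_embed(X[i, ], cfg0, par0), H[i, ])
  expect_error(mil_embed(random_bag(3, 10), cfg0, par0),
               "contract violation")
})

test_that("attention weights are a softmax over the bag", {
  H1 <- mil_embed(withr::with_seed(2, random_bag(1, 24)), cfg0, par0)
  expect_equal(attention_scores(H1, cfg0, par0)$weights, 1)
  H5 <- mil_embed(matrix(rep(withr::with_seed(3, rnorm(24)), 5), 5,
                         byrow = TRUE), cfg0, par0)
  expect_equal(attention_scores(H5, cfg0, par0)$weights, rep(0.2, 5),
               tolerance = 1e-12)
  for (i in 1:5) {
    a <- attention_scores(mil_embed(random_bag(sample(2:40, 1), 24),
                                    cfg0, par0), cfg0, par0)
    expect_equal(sum(a$weights), 1, tolerance = 1e-6)
    expect_true(all(a$weights >= 0))
  }
})

test_that("pooling is the attention-weighted sum with its invariances", {
  H <- mil_embed(withr::with_seed(4, random_bag(8, 24)), cfg0, par0)
  expect_equal(attention_pool(H, rep(1 / 8, 8)), colMeans(H))
  onehot <- c(0, 0, 1, 0, 0, 0, 0, 0)
  expect_equal(attention_pool(H, onehot), as.numeric(H[3, ]))
  # duplicating every instance leaves the pooled vector unchanged
  Hd <- rbind(H, H)
  ad <- attention_scores(Hd, cfg0, par0)
  a <- attention_scores(H, cfg0, par0)
  expect_equal(attention_pool(Hd, ad), attention_pool(H, a),
               tolerance = 1e-6)
  # direct recomputation oracle
  expect_equal(attention_pool(H, a),
               as.numeric(t(H) %*% a$weights), tolerance = 1e-12)
  expect_error(attention_pool(H, rep(0.5, 3)), "contract violation")
})

test_that("classification emits K probabilities with tie-break to the lowest rank", {
  z <- withr::with_seed(5, rnorm(cfg0$embed_dim))
  pred <- mil_classify(z, cfg0, par0, scheme = grading_scheme(3))
  expect_length(pred$prob, 4)
  expect_equal(sum(pred$prob), 1, tolerance = 1e-9)
  cfg3 <- tiny_config(K = 3, D = 24)
  pred3 <- mil_classify(z, cfg3, milgrade:::mil_init(cfg3),
                        scheme = grading_scheme(2))
  expect_length(pred3$prob, 3)
  # all-equal logits: uniform probabilities, least severe grade wins
  pz <- par0
  pz$Wc2[] <- 0; pz$bc2[] <- 0
  predz <- mil_classify(z, cfg0, pz)
  expect_equal(predz$prob, rep(0.25, 4), tolerance = 1e-12)
  expect_equal(predz$rank, 0L)
})

test_that("slide-level outputs are permutation invariant, attention permutes along", {
  X <- withr::with_seed(6, random_bag(20, 24))
  fw <- mil_forward(X, cfg0, par0)
  for (r in 1:25) {
    i <- sample(20)
    fw2 <- mil_forward(X[i, ], cfg0, par0)
    expect_lt(max(abs(fw$prediction$prob - fw2$prediction$prob)), 1e-6)
    expect_equal(fw2$attention$weights, fw$attention$weights[i],
                 tolerance = 1e-9)
  }
  # identical-instance bag: uniform attention, same prediction as one instance
  Xc <- matrix(rep(X[1, ], 7), 7, byrow = TRUE)
  fwc <- mil_forward(Xc, cfg0, par0)
  expect_equal(fwc$attention$weights, rep(1 / 7, 7), tolerance = 1e-12)
  fw1 <- mil_forward(X[1, , drop = FALSE], cfg0, par0)
  expect_equal(fwc$prediction$prob, fw1$prediction$prob, tolerance = 1e-9)
  # determinism
  expect_identical(mil_forward(X, cfg0, par0)$prediction$prob,
                   fw$prediction$prob)
})

test_that("the single-precision core agrees with the double-precision reference", {
  for (i in 1:10) {
    K <- sample(c(3L, 4L), 1)
    cfg <- tiny_config(K = K, D = 24, seed = i)
    par <- milgrade:::mil_init(cfg)
    X <- random_bag(sample(2:50, 1), 24)
    ref <- mil_forward(X, cfg, par)
    fast <- milgrade:::.mil_predict_cpp(list(X), par, cfg$gated)
    expect_equal(as.numeric(fast$prob), ref$prediction$prob,
                 tolerance = 1e-5)
    expect_equal(as.numeric(fast$attention[[1]]), ref$attention$weights,
                 tolerance = 1e-5)
  }
  # ungated variant too
  cfgu <- tiny_config(K = 3, D = 24, seed = 99)
  cfgu$gated <- FALSE
  paru <- milgrade:::mil_init(cfgu)
  X <- withr::with_seed(7, random_bag(12, 24))
  expect_equal(as.numeric(milgrade:::.mil_predict_cpp(list(X), paru,
                                                      FALSE)$prob),
               mil_forward(X, cfgu, paru)$prediction$prob,
               tolerance = 1e-5)
})

test_that("training gradients match finite differences of the reference loss", {
  cfg <- mil_config(input_dim = 10, embed_dim = 6, attn_dim = 4,
                    penultimate_dim = 5, n_classes = 3, dropout = 0,
                    reduce_dim = NULL, seed = 21)
  par <- milgrade:::mil_init(cfg)
  bags <- withr::with_seed(8, lapply(1:3, function(i) random_bag(4, 10)))
  y <- c(0L, 2L, 1L); w <- c(1, 1.4, 0.6)
  lossR <- function(p) {
    tot <- 0
    for (b in seq_along(bags)) {
      fw <- mil_forward(bags[[b]], cfg, p)
      tot <- tot + w[b] / length(bags) *
        (-log(fw$prediction$prob[y[b] + 1]))
    }
    tot
  }
  g <- milgrade:::.mil_grad_cpp(bags, y, par, TRUE, w)
  expect_equal(g$loss, lossR(par), tolerance = 1e-5)
  eps <- 1e-5
  for (nm in c("W1", "Wv", "Wu", "w", "Wc1", "Wc2", "b1", "bc2")) {
    idx <- withr::with_seed(30 + match(nm, names(par)),
                            sample(length(par[[nm]]),
                                   min(4, length(par[[nm]]))))
    for (i in idx) {
      up <- par; up[[nm]][i] <- up[[nm]][i] + eps
      dn <- par; dn[[nm]][i] <- dn[[nm]][i] - eps
      fd <- (lossR(up) - lossR(dn)) / (2 * eps)
      expect_lt(abs(as.numeric(g[[nm]])[i] - fd),
                1e-4 * max(1, abs(fd)))
    }
  }
})
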