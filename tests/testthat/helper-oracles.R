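# Brute-force oracles, independent of the package implementations.

# AUC by exhaustive pair enumeration (ties count 1/2)
oracle_auc <- function(truth01, score) {
  pos <- score[truth01 == 1]
  neg <- score[truth01 == 0]
  if (!length(pos) || !length(neg)) return(NA_real_)
  tot <- 0
  for (p in pos) tot <- tot + sum(p > neg) + 0.5 * sum(p == neg)
  tot / (length(pos) * length(neg))
}

# quadratic weighted kappa by direct O/E tabulation
oracle_qwk <- function(r1, r2, K) {
  n <- length(r1)
  O <- matrix(0, K, K)
  for (i in seq_len(n)) O[r1[i] + 1, r2[i] + 1] <- O[r1[i] + 1, r2[i] + 1] + 1
  W <- matrix(0, K, K)
  for (i in 1:K) for (j in 1:K) W[i, j] <- (i - j)^2 / (K - 1)^2
  E <- (rowSums(O) %o% colSums(O)) / n
  1 - sum(W * O) / sum(W * E)
}

# textbook 2x2 chi-squared, optionally Yates-corrected
oracle_chi2 <- function(a, b, c, d, yates) {
  N <- a + b + c + d
  num <- if (yates) N * max(0, abs(a * d - b * c) - N / 2)^2
         else N * (a * d - b * c)^2
  num / ((a + b) * (c + d) * (a + c) * (b + d))
}

# one-vs-rest counts straight from the vectors
oracle_cui <- function(truth, pred, k) {
  tp <- sum(truth == k & pred == k)
  fn <- sum(truth == k & pred != k)
  fp <- sum(truth != k & pred == k)
  tn <- sum(truth != k & pred != k)
  list(cui_plus = (tp / (tp + fn)) * (tp / (tp + fp)),
       cui_minus = (tn / (tn + fp)) * (tn / (tn + fn)))
}

random_prob_matrix <- function(n, K) {
  m <- matrix(stats::rexp(n * K), n, K)
  m / rowSums(m)
}

# small random feature bag
random_bag <- function(M, D, sd = 1) matrix(stats::rnorm(M * D, sd = sd), M, D)

tiny_config <- function(K = 4, D = 24, seed = 1, dropout = 0.25) {
  mil_config(input_dim = D, embed_dim = 12, attn_dim = 8,
             penultimate_dim = 6, n_classes = K, dropout = dropout,
             reduce_dim = NULL, seed = seed)
}

tiny_spec <- function(...) {
  cohort_spec(n_features = 24, bag_size = c(10, 30), ...)
}
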