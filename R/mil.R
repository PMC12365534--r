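#' Network configuration for the attention-MIL grader
#'
#' The network is the standard attention-based MIL stack: a per-instance
#' feature module (one ReLU layer, 1,024 -> 512, with dropout during
#' training), a gated attention module (tanh x sigmoid branches of width
#' 256 feeding a scalar score per instance), softmax-normalized
#' attention pooling, and a classifier head (512 -> 128 -> K).  The
#' 128-wide penultimate layer is consistent with the one-output-unit
#' FLOPs gap between the ternary and quaternary heads of the deployed
#' model.
#'
#' @param input_dim Patch-feature dimension D (1,024 for ResNet50
#'   features).
#' @param embed_dim High-level feature dimension E.
#' @param attn_dim Attention hidden width A.
#' @param penultimate_dim Classifier hidden width P.
#' @param n_classes K (3 for ternary tasks, 4 for quaternary).
#' @param gated Use the gated (tanh x sigmoid) attention form.
#' @param dropout Dropout rate on the embedding during training.
#' @param reduce_dim The feature module opens with a frozen, data-driven
#'   compression: the leading principal axes of the pooled training
#'   instances.  Deep patch features concentrate their class-relevant
#'   structure in a few directions of excess variance, while the
#'   remaining axes carry near-isotropic noise whose per-slide averages
#'   act as slide fingerprints; discarding them prevents the classifier
#'   from memorizing slides instead of lesions.  `"auto"` (the default)
#'   keeps the axes whose eigenvalues exceed the Marchenko--Pastur noise
#'   edge of the instance covariance (floored at 8, capped at 256); an
#'   integer fixes the count; `NULL` (or any value `>= input_dim`)
#'   disables compression.
#' @param seed Seed for parameter initialization.
#' @return An object of class `mil_config`.
#' @export
mil_config <- function(input_dim = 1024L, embed_dim = 512L, attn_dim = 256L,
                       penultimate_dim = 128L, n_classes = 4L, gated = TRUE,
                       dropout = 0.25, reduce_dim = "auto", seed = 1L) {
  if (is.null(reduce_dim)) reduce_dim <- as.integer(input_dim)
  if (!identical(reduce_dim, "auto"))
    reduce_dim <- min(as.integer(reduce_dim), as.integer(input_dim))
  cfg <- list(input_dim = as.integer(input_dim),
              reduce_dim = reduce_dim,
              embed_dim = as.integer(embed_dim),
              attn_dim = as.integer(attn_dim),
              penultimate_dim = as.integer(penultimate_dim),
              n_classes = as.integer(n_classes),
              gated = isTRUE(gated), dropout = dropout,
              seed = as.integer(seed))
  stopifnot(cfg$input_dim >= 1, cfg$embed_dim >= 1,
            cfg$attn_dim >= 1, cfg$penultimate_dim >= 1,
            cfg$n_classes %in% c(3L, 4L), dropout >= 0, dropout < 1)
  if (!identical(reduce_dim, "auto")) stopifnot(cfg$reduce_dim >= 1)
  structure(cfg, class = "mil_config")
}

# Fit the frozen compression stage: leading principal axes of the pooled
# training instances (deterministic: instances subsampled by stride, eigen
# signs fixed).  In "auto" mode the kept count is the number of
# eigenvalues above the Marchenko-Pastur bulk edge sigma^2 (1+sqrt(D/N))^2
# with sigma^2 the median eigenvalue, floored at 8 and capped at 256.
# Returns list(P, q); P is NULL when no compression applies.
fit_reducer <- function(bags, config, max_instances = 60000L) {
  q <- config$reduce_dim
  if (!identical(q, "auto") && q >= config$input_dim)
    return(list(P = NULL, q = config$input_dim))
  cp <- .instance_crossprod_cpp(bags, as.integer(max_instances))
  ev <- eigen(cp$S / cp$n, symmetric = TRUE)
  if (identical(q, "auto")) {
    sigma2 <- stats::median(ev$values)
    edge <- sigma2 * (1 + sqrt(config$input_dim / cp$n))^2
    q <- min(max(sum(ev$values > edge), 8L), 256L, config$input_dim)
    if (q >= config$input_dim) return(list(P = NULL, q = config$input_dim))
  }
  P <- ev$vectors[, seq_len(q), drop = FALSE]
  sgn <- ifelse(colSums(P) < 0, -1, 1)
  list(P = sweep(P, 2, sgn, "*"), q = q)
}

# apply the compression stage to a raw M x D matrix
reduce_bag <- function(X, params) {
  if (is.null(params$P)) X else X %*% params$P
}

# He/Glorot-style initialization, deterministic in config$seed
mil_init <- function(config) {
  q <- if (identical(config$reduce_dim, "auto")) config$input_dim
       else config$reduce_dim
  withr::with_seed(config$seed, {
    gl <- function(nin, nout)
      matrix(rnorm(nin * nout, sd = sqrt(2 / (nin + nout))), nin, nout)
    list(
      W1 = gl(q, config$embed_dim),
      b1 = rep(0, config$embed_dim),
      Wv = gl(config$embed_dim, config$attn_dim),
      bv = rep(0, config$attn_dim),
      Wu = gl(config$embed_dim, config$attn_dim),
      bu = rep(0, config$attn_dim),
      w  = as.numeric(gl(config$attn_dim, 1L)),
      c  = 0,
      Wc1 = gl(config$embed_dim, config$penultimate_dim),
      bc1 = rep(0, config$penultimate_dim),
      Wc2 = gl(config$penultimate_dim, config$n_classes),
      bc2 = rep(0, config$n_classes))
  })
}

softmax_vec <- function(s) {
  e <- exp(s - max(s))
  e / sum(e)
}

#' Per-instance embedding (feature module)
#'
#' Row-wise ReLU layer mapping raw patch features to high-level
#' features; instances never mix, so permuting bag rows permutes the
#' output identically.
#'
#' @param bag A [feature_bag()] or M x D matrix.
#' @param config A [mil_config()].
#' @param params Parameter list from a fitted model (`coef()`) or
#'   `mil_init()`.
#' @return M x E matrix.
#' @export
mil_embed <- function(bag, config, params) {
  X <- if (inherits(bag, "feature_bag")) bag$features else as.matrix(bag)
  if (ncol(X) != config$input_dim)
    stop("contract violation: bag dimension ", ncol(X),
         " != config input_dim ", config$input_dim, call. = FALSE)
  X <- reduce_bag(X, params)
  H <- X %*% params$W1
  H <- sweep(H, 2, params$b1, "+")
  H[H < 0] <- 0
  H
}

#' Attention scores over a bag
#'
#' Gated attention: `s_i = w' (tanh(Wv' h_i) * sigmoid(Wu' h_i)) + c`,
#' normalized over the bag by softmax.  With `gated = FALSE` the sigmoid
#' gate is dropped.
#'
#' @param H M x E embedding matrix from [mil_embed()].
#' @param config,params As in [mil_embed()].
#' @param coords Optional coordinates carried into the map.
#' @param slide_id Identifier carried into the map.
#' @return An `attention_map`: `weights` (softmax-normalized, sum 1),
#'   `raw` scores, `coords`, `slide_id`.
#' @export
attention_scores <- function(H, config, params, coords = NULL,
                             slide_id = "slide") {
  H <- as.matrix(H)
  Av <- tanh(sweep(H %*% params$Wv, 2, params$bv, "+"))
  G <- if (config$gated) {
    Au <- 1 / (1 + exp(-sweep(H %*% params$Wu, 2, params$bu, "+")))
    Av * Au
  } else Av
  raw <- as.numeric(G %*% params$w + params$c)
  structure(list(slide_id = slide_id, weights = softmax_vec(raw),
                 raw = raw, coords = coords),
            class = "attention_map")
}

#' @export
print.attention_map <- function(x, ...) {
  cat(sprintf("attention_map '%s': %d instances, sum %.6f, max %.4f\n",
              x$slide_id, length(x$weights), sum(x$weights),
              max(x$weights)))
  invisible(x)
}

#' Attention-weighted pooling
#'
#' Slide-level vector `z = sum_i a_i h_i` (the dot product of attention
#' scores and high-level features).
#'
#' @param H M x E embedding matrix.
#' @param attn An `attention_map` (or numeric weight vector).
#' @return Numeric vector of length E.
#' @export
attention_pool <- function(H, attn) {
  a <- if (inherits(attn, "attention_map")) attn$weights else as.numeric(attn)
  H <- as.matrix(H)
  if (length(a) != nrow(H))
    stop("contract violation: attention length ", length(a),
         " != bag size ", nrow(H), call. = FALSE)
  as.numeric(crossprod(H, a))
}

#' Classify a pooled slide vector
#'
#' @param z Slide-level vector of length E.
#' @param config,params As in [mil_embed()].
#' @param scheme Optional [grading_scheme()] used to label classes.
#' @param slide_id Identifier carried into the prediction.
#' @return A `grade_prediction`: `prob` (length K, sums to 1), `logits`,
#'   `rank` (argmax, ties broken toward the least severe grade),
#'   `class` when a scheme is given.
#' @export
mil_classify <- function(z, config, params, scheme = NULL,
                         slide_id = "slide") {
  h1 <- as.numeric(z %*% params$Wc1) + params$bc1
  h1[h1 < 0] <- 0
  logits <- as.numeric(h1 %*% params$Wc2) + params$bc2
  prob <- softmax_vec(logits)
  rank <- which.max(prob) - 1L   # which.max takes the first (lowest) maximum
  structure(
    list(slide_id = slide_id,
         task_id = if (!is.null(scheme)) scheme$task_id else NA_integer_,
         prob = prob, logits = logits, rank = rank,
         class = if (!is.null(scheme)) scheme$classes[rank + 1L]
                 else NA_character_),
    class = "grade_prediction")
}

#' @export
print.grade_prediction <- function(x, ...) {
  cat(sprintf("grade_prediction '%s': rank %d%s\n", x$slide_id, x$rank,
              if (!is.na(x$class)) paste0(" (", x$class, ")") else ""))
  cat("  prob:", paste(sprintf("%.3f", x$prob), collapse = " "), "\n")
  invisible(x)
}

#' Full forward pass: bag to grade prediction and attention map
#'
#' Composition embed -> attention -> pool -> classify.  Slide-level
#' outputs are invariant to any permutation of the bag rows; the
#' attention map permutes with them.
#'
#' @inheritParams mil_embed
#' @param scheme Optional [grading_scheme()].
#' @return List with `prediction` (a `grade_prediction`) and `attention`
#'   (an `attention_map`).
#' @export
mil_forward <- function(bag, config, params, scheme = NULL) {
  sid <- if (inherits(bag, "feature_bag")) bag$slide_id else "bag"
  coords <- if (inherits(bag, "feature_bag")) bag$coords else NULL
  H <- mil_embed(bag, config, params)
  attn <- attention_scores(H, config, params, coords = coords,
                           slide_id = sid)
  z <- attention_pool(H, attn)
  pred <- mil_classify(z, config, params, scheme = scheme, slide_id = sid)
  list(prediction = pred, attention = attn)
}
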