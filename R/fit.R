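#' Fit an attention-MIL grading model
#'
#' Trains the gated attention multiple-instance network on a set of
#' feature bags with slide-level ordinal grade labels.  Training uses
#' bag batch size 1 with Adam and the imbalance-aware rebalanced
#' cross-entropy by default; all randomness (initialization, shuffling,
#' dropout) is controlled by the seeds in `config` and `train`, and a
#' rerun with identical inputs reproduces the parameters exactly.
#'
#' @param bags List of [feature_bag()] objects (plain M x D matrices are
#'   accepted).
#' @param labels Grade labels: integer ranks `0..K-1`, or class names
#'   from the scheme.
#' @param scheme A [grading_scheme()].
#' @param config A [mil_config()]; `n_classes` must match the scheme.
#' @param train A [train_config()].
#' @param params Optional warm-start parameter list (used by
#'   [fine_tune()]); defaults to fresh initialization.
#' @param state Optional [loss_state()] carried over from earlier
#'   training.
#' @return An object of class `mil_grader` with elements `params`,
#'   `config`, `scheme`, `train`, `loss_history` (mean weighted loss per
#'   epoch), `loss_state`, `n_train`.
#' @seealso [predict.mil_grader()], [mil_crossval()], [fine_tune()]
#' @examples
#' spec <- cohort_spec(n_features = 32, bag_size = c(8, 16))
#' coh <- generate_cohort(spec, 40, seed = 1)
#' fit <- mil_grader(coh$bags, coh$labels$grade, grading_scheme(3),
#'                   mil_config(32, 16, 8, 8, seed = 1),
#'                   train_config(epochs = 2, seed = 1))
#' predict(fit, coh$bags[1:3])
#' @export
mil_grader <- function(bags, labels, scheme,
                       config = mil_config(n_classes = scheme$K),
                       train = train_config(),
                       params = NULL, state = NULL) {
  stopifnot(inherits(scheme, "grading_scheme"),
            inherits(config, "mil_config"),
            inherits(train, "train_config"))
  if (config$n_classes != scheme$K)
    stop("config n_classes (", config$n_classes,
         ") does not match scheme K (", scheme$K, ")", call. = FALSE)
  X <- bag_matrices(bags, config$input_dim)
  if (length(X) == 0L) stop("no training bags", call. = FALSE)
  y <- as_ranks(labels, scheme)
  if (length(y) != length(X))
    stop("labels length does not match bags", call. = FALSE)
  if (is.null(params)) {
    red <- fit_reducer(X, config)
    config$reduce_dim <- red$q
    params <- mil_init(config)
    params$P <- red$P
  } else if (identical(config$reduce_dim, "auto")) {
    config$reduce_dim <- if (is.null(params$P)) config$input_dim
                         else ncol(params$P)
  }
  P <- params$P
  if (!is.null(P)) X <- lapply(X, function(m) m %*% P)
  if (is.null(state)) state <- loss_state(scheme$K, train$ema_decay,
                                          train$eps)
  if (train$epochs == 0L) {
    res <- list(params = params[setdiff(names(params), "P")],
                epoch_loss = numeric(),
                stat = state$stat, count = state$count)
  } else {
    res <- .mil_train_cpp(X, y, params, config$gated, config$dropout,
                          config$n_classes, train$loss, state$decay,
                          state$eps, state$stat, state$count,
                          train$epochs, train$lr, train$weight_decay,
                          train$accum, train$seed)
  }
  state$stat <- as.numeric(res$stat)
  state$count <- as.numeric(res$count)
  out_params <- res$params
  out_params$P <- P
  structure(
    list(params = out_params, config = config, scheme = scheme,
         train = train, loss_history = as.numeric(res$epoch_loss),
         loss_state = state, n_train = length(X), call = match.call()),
    class = "mil_grader")
}

# normalize a list of bags/matrices to plain matrices, checking dimension
bag_matrices <- function(bags, input_dim) {
  if (inherits(bags, "feature_bag") || is.matrix(bags)) bags <- list(bags)
  lapply(bags, function(b) {
    m <- if (inherits(b, "feature_bag")) b$features else as.matrix(b)
    if (ncol(m) != input_dim)
      stop("contract violation: bag dimension ", ncol(m),
           " != config input_dim ", input_dim, call. = FALSE)
    m
  })
}

bag_ids <- function(bags) {
  vapply(seq_along(bags), function(i) {
    b <- bags[[i]]
    if (inherits(b, "feature_bag")) b$slide_id else sprintf("bag_%04d", i)
  }, "")
}

#' @export
print.mil_grader <- function(x, ...) {
  cat(sprintf("Attention-MIL grader: task %d (%s), %d classes\n",
              x$scheme$task_id, x$scheme$task_name, x$scheme$K))
  cat(sprintf("  %d -> %d -> (attn %d%s) -> %d -> %d, dropout %.2f\n",
              x$config$input_dim, x$config$embed_dim, x$config$attn_dim,
              if (x$config$gated) ", gated" else "",
              x$config$penultimate_dim, x$config$n_classes,
              x$config$dropout))
  cat(sprintf("  trained on %d bags, %d epochs, loss '%s'",
              x$n_train, length(x$loss_history), x$train$loss))
  if (length(x$loss_history))
    cat(sprintf(", final loss %.4f", tail(x$loss_history, 1)))
  cat("\n")
  invisible(x)
}

#' @export
summary.mil_grader <- function(object, ...) {
  print(object)
  if (length(object$loss_history)) {
    cat("  loss by epoch:",
        paste(sprintf("%.3f", object$loss_history), collapse = " "), "\n")
  }
  cat("  class gradient statistics (EMA):",
      paste(sprintf("%.3f", object$loss_state$stat), collapse = " "), "\n")
  cat("  class sample counts:",
      paste(object$loss_state$count, collapse = " "), "\n")
  invisible(object)
}

#' @export
coef.mil_grader <- function(object, ...) object$params

#' Plot the training loss curve
#'
#' @param x A fitted [mil_grader()].
#' @param ... Passed to [plot()].
#' @export
plot.mil_grader <- function(x, ...) {
  if (!length(x$loss_history)) {
    warning("no training history to plot")
    return(invisible(x))
  }
  plot(seq_along(x$loss_history), x$loss_history, type = "b",
       xlab = "epoch", ylab = "mean weighted loss",
       main = sprintf("task %d (%s)", x$scheme$task_id,
                      x$scheme$task_name), ...)
  invisible(x)
}

#' Predict grades (and attention) for new bags
#'
#' @param object A fitted [mil_grader()].
#' @param newdata A `feature_bag`, matrix, or list of them.
#' @param type `"response"` for a per-slide data frame of probabilities
#'   and predicted ranks, `"prob"` for the bare probability matrix,
#'   `"attention"` to also return per-bag `attention_map`s.
#' @param ... Unused.
#' @return For `"response"`: data frame with `slide_id`, `p_0..p_{K-1}`,
#'   `rank`, `class`.  For `"attention"`: list with `response` and
#'   `attention`.
#' @export
predict.mil_grader <- function(object, newdata,
                               type = c("response", "prob", "attention"),
                               ...) {
  type <- match.arg(type)
  single <- inherits(newdata, "feature_bag") || is.matrix(newdata)
  bags <- if (single) list(newdata) else newdata
  X <- bag_matrices(bags, object$config$input_dim)
  if (!is.null(object$params$P))
    X <- lapply(X, function(m) m %*% object$params$P)
  res <- .mil_predict_cpp(X, object$params, object$config$gated)
  prob <- res$prob
  colnames(prob) <- paste0("p_", seq_len(object$scheme$K) - 1L)
  if (type == "prob") return(prob)
  rank <- max.col(prob, ties.method = "first") - 1L
  out <- data.frame(slide_id = bag_ids(bags), prob,
                    rank = rank,
                    class = object$scheme$classes[rank + 1L],
                    row.names = NULL, check.names = FALSE)
  if (type == "response") return(out)
  attn <- lapply(seq_along(bags), function(i) {
    b <- bags[[i]]
    structure(list(slide_id = out$slide_id[i],
                   weights = as.numeric(res$attention[[i]]),
                   raw = as.numeric(res$attention_raw[[i]]),
                   coords = if (inherits(b, "feature_bag")) b$coords
                            else NULL),
              class = "attention_map")
  })
  list(response = out, attention = attn)
}

#' Stratified k-fold cross-validated training
#'
#' Trains one model per fold on the other k-1 folds and evaluates it on
#' the held-out fold, mirroring the 5-fold protocol used to develop the
#' grading model.  Out-of-fold predictions are pooled into a single
#' evaluation report, and the best fold (by held-out macro-AUC) is
#' flagged for downstream fine-tuning.
#'
#' @inheritParams mil_grader
#' @param k Number of folds (ignored when `plan` is given).
#' @param plan Optional precomputed [make_folds()] plan.
#' @param seed Seed for the fold plan.
#' @param keep_models Keep the per-fold fitted models (set `FALSE` to
#'   save memory when only metrics are needed; the best fold's model is
#'   always kept).
#' @return An object of class `mil_cv`: `plan`, `models`, `oof`
#'   (out-of-fold predictions with truth), `report` (pooled
#'   [compute_report()]), `per_fold` (per-fold reports), `best_fold`.
#' @export
mil_crossval <- function(bags, labels, scheme,
                         config = mil_config(n_classes = scheme$K),
                         train = train_config(), k = 5L, plan = NULL,
                         seed = 1L, keep_models = TRUE) {
  y <- as_ranks(labels, scheme)
  ids <- bag_ids(bags)
  if (is.null(plan)) plan <- make_folds(setNames(y, ids), k = k, seed = seed)
  stopifnot(nrow(plan) == length(bags))
  folds <- sort(unique(plan$fold))
  models <- vector("list", length(folds))
  per_fold <- vector("list", length(folds))
  oof <- vector("list", length(folds))
  for (fi in seq_along(folds)) {
    f <- folds[fi]
    tr <- which(plan$fold != f); va <- which(plan$fold == f)
    fit <- mil_grader(bags[tr], y[tr], scheme, config, train)
    pred <- predict(fit, bags[va])
    prob <- as.matrix(pred[, paste0("p_", scheme$ranks)])
    rep_f <- compute_report(y[va], prob, scheme)
    per_fold[[fi]] <- rep_f
    oof[[fi]] <- data.frame(slide_id = ids[va], fold = f, truth = y[va],
                            pred, row.names = NULL, check.names = FALSE)
    models[[fi]] <- fit
  }
  oof <- do.call(rbind, oof)
  prob_all <- as.matrix(oof[, paste0("p_", scheme$ranks)])
  pooled <- compute_report(oof$truth, prob_all, scheme)
  fold_auc <- vapply(per_fold, function(r) r$macro_auc, 0)
  best <- folds[which.max(fold_auc)]
  if (!keep_models)
    models[setdiff(seq_along(folds), which.max(fold_auc))] <- list(NULL)
  structure(list(plan = plan, models = models, oof = oof, report = pooled,
                 per_fold = per_fold, best_fold = best,
                 scheme = scheme, config = config, train = train),
            class = "mil_cv")
}

#' @export
print.mil_cv <- function(x, ...) {
  k <- length(x$per_fold)
  auc <- vapply(x$per_fold, function(r) r$macro_auc, 0)
  acc <- vapply(x$per_fold, function(r) r$accuracy, 0)
  cat(sprintf("%d-fold cross-validated attention-MIL grader (task %d, %s)\n",
              k, x$scheme$task_id, x$scheme$task_name))
  cat(sprintf("  macro-AUC %.3f +/- %.3f, ACC %.3f +/- %.3f (fold mean +/- SD)\n",
              mean(auc), stats::sd(auc), mean(acc), stats::sd(acc)))
  cat(sprintf("  pooled out-of-fold: macro-AUC %.3f, ACC %.3f; best fold %d\n",
              x$report$macro_auc, x$report$accuracy, x$best_fold))
  invisible(x)
}

#' @export
summary.mil_cv <- function(object, ...) {
  print(object)
  cat("\nPooled out-of-fold report:\n")
  print(object$report)
  invisible(object)
}

#' Extract the best-fold model from a cross-validation run
#'
#' @param cv A [mil_crossval()] result.
#' @return The `mil_grader` trained on the folds complementary to the
#'   best-performing held-out fold.
#' @export
best_model <- function(cv) {
  stopifnot(inherits(cv, "mil_cv"))
  cv$models[[which(sort(unique(cv$plan$fold)) == cv$best_fold)]]
}

#' Fine-tune a fitted grader on a new cohort
#'
#' Resumes training from the fitted parameters -- the antrum-to-corpus
#' workflow: the best cross-validation fold model is adapted to corpus
#' slides, whose glandular architecture differs from antrum despite the
#' shared mucosal organization.  With `epochs = 0` the model is returned
#' with its predictions unchanged.
#'
#' With `val_frac > 0` the new cohort is split (seeded) into a tuning
#' and a validation part, the model is checkpointed after every epoch,
#' and the checkpoint with the best validation accuracy is adopted --
#' including the un-tuned starting model, which is only abandoned when
#' some checkpoint beats it by more than `min_gain`.  This is the
#' guarded adaptation used in the transfer experiment: fine-tuning must
#' never silently degrade a model that already transfers well.
#'
#' @param object A fitted [mil_grader()].
#' @param bags,labels The new cohort.
#' @param train A [train_config()] for the fine-tuning phase; defaults
#'   to the original one with 5 epochs at a tenth of the learning rate
#'   (adaptation should refine the fitted solution, not re-train it).
#' @param val_frac Fraction of the new cohort held out for checkpoint
#'   selection; 0 disables selection and returns the final epoch.
#' @param min_gain Minimum validation-accuracy gain over the starting
#'   model required to adopt a fine-tuned checkpoint.
#' @return A new `mil_grader`.
#' @export
fine_tune <- function(object, bags, labels, train = NULL, val_frac = 0,
                      min_gain = 0.03) {
  stopifnot(inherits(object, "mil_grader"))
  if (is.null(train)) {
    train <- object$train
    train$epochs <- 5L
    train$lr <- train$lr / 10
  }
  y <- as_ranks(labels, object$scheme)   # scheme mismatch -> error here
  if (val_frac <= 0 || train$epochs == 0L)
    return(mil_grader(bags, y, object$scheme, object$config, train,
                      params = object$params, state = object$loss_state))
  n <- length(bags)
  nv <- max(1L, round(val_frac * n))
  va <- withr::with_seed(train$seed, sample.int(n, nv))
  tr_idx <- setdiff(seq_len(n), va)
  val_acc <- function(model)
    mean(predict(model, bags[va])$rank == y[va])
  best <- object
  best_acc <- val_acc(object)
  base_acc <- best_acc
  cur <- object
  one <- train
  one$epochs <- 1L
  for (ep in seq_len(train$epochs)) {
    one$seed <- train$seed + ep
    cur <- mil_grader(bags[tr_idx], y[tr_idx], object$scheme,
                      object$config, one,
                      params = cur$params, state = cur$loss_state)
    acc <- val_acc(cur)
    if (acc > best_acc && acc >= base_acc + min_gain) {
      best <- cur
      best_acc <- acc
    }
  }
  best
}

CHECKPOINT_SCHEMA <- "milgrade/checkpoint/1"

#' Save / load a model checkpoint
#'
#' Checkpoints embed the full model configuration and grading scheme, so
#' a loaded model predicts identically to the saved one.
#'
#' @param object A fitted [mil_grader()].
#' @param path Checkpoint file path.
#' @export
save_checkpoint <- function(object, path) {
  stopifnot(inherits(object, "mil_grader"))
  saveRDS(list(schema = CHECKPOINT_SCHEMA, model = object), path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  obj <- tryCatch(readRDS(path), error = function(e)
    stop("format error: cannot read checkpoint: ", conditionMessage(e),
         call. = FALSE))
  if (!is.list(obj) || !identical(obj$schema, CHECKPOINT_SCHEMA))
    stop("format error: schema-version mismatch in checkpoint",
         call. = FALSE)
  obj$model
}
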