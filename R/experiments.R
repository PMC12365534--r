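#' Label-recovery experiment on a synthetic graded cohort
#'
#' The package's reference validation experiment: simulate a quaternary
#' cohort with the long-tailed antrum-atrophy grade priors, run
#' stratified 5-fold cross-validated training, and measure (a) held-out
#' grading performance and (b) how well the attention weights localize
#' the ground-truth lesion instances of the held-out bags.
#'
#' @param n Cohort size.
#' @param cohort_seed Seed for cohort generation (the study condition;
#'   independent of the training seed).
#' @param seed Seed for fold assignment, initialization and training.
#' @param epochs Training epochs per fold.
#' @param k Folds.
#' @param spec Cohort specification; defaults to [cohort_spec()].
#' @param config,train Model and training configuration overrides.
#' @return List with `cv` (a [mil_crossval()] result), `localization`
#'   (pooled instance-level attention metrics from
#'   [attention_localization()]), `fold_macro_auc`, `fold_accuracy`
#'   (per-fold vectors), and their means.
#' @export
label_recovery_experiment <- function(n = 800, cohort_seed = 7, seed = 7,
                                      epochs = 10, k = 5,
                                      spec = cohort_spec(),
                                      config = NULL, train = NULL) {
  scheme <- grading_scheme(3)
  stopifnot(spec$K == scheme$K)
  coh <- generate_cohort(spec, n, seed = cohort_seed)
  if (is.null(config)) config <- mil_config(n_classes = scheme$K,
                                            seed = as.integer(seed))
  if (is.null(train)) train <- train_config(epochs = as.integer(epochs),
                                            seed = as.integer(seed))
  cv <- mil_crossval(coh$bags, coh$labels$grade, scheme, config, train,
                     k = k, seed = as.integer(seed))
  attns <- list(); labs <- list()
  folds <- sort(unique(cv$plan$fold))
  for (fi in seq_along(folds)) {
    va <- which(cv$plan$fold == folds[fi])
    pa <- predict(cv$models[[fi]], coh$bags[va], type = "attention")
    attns <- c(attns, pa$attention)
    labs <- c(labs, lapply(coh$bags[va], function(b) b$instance_labels))
  }
  loc <- attention_localization(attns, labs)
  fa <- vapply(cv$per_fold, function(r) r$macro_auc, 0)
  fc <- vapply(cv$per_fold, function(r) r$accuracy, 0)
  list(cv = cv, localization = loc,
       fold_macro_auc = fa, fold_accuracy = fc,
       macro_auc = mean(fa), accuracy = mean(fc),
       pooled_macro_auc = cv$report$macro_auc,
       pooled_accuracy = cv$report$accuracy)
}

#' Antrum-to-corpus transfer experiment
#'
#' Trains a grader on an "antrum" cohort, then simulates the corpus
#' cohort as a rigid shift of both instance archetypes (offset norm 0.5)
#' combined with the corpus grade priors (heavily normal-dominated, as
#' corpus atrophy is far rarer than antrum atrophy), and measures
#' held-out corpus accuracy before and after fine-tuning, over several
#' seeds.
#'
#' @param seeds Seeds, one paired comparison per seed.
#' @param n_pretrain,n_tune,n_test Cohort sizes for antrum pretraining,
#'   corpus fine-tuning, and corpus evaluation (the tune size sits at
#'   the scale of the reference corpus cohort).
#' @param shift_norm Euclidean norm of the archetype offset.
#' @param epochs Antrum pretraining epochs.
#' @param corpus_priors Grade priors of the simulated corpus cohort.
#' @return Data frame with one row per seed: `seed`, `pre_accuracy`,
#'   `post_accuracy`, `improved` (post >= pre).
#' @export
corpus_transfer_experiment <- function(seeds = 1:5, n_pretrain = 250,
                                       n_tune = 300, n_test = 150,
                                       shift_norm = 0.5, epochs = 10,
                                       corpus_priors = c(0.791, 0.089,
                                                         0.073, 0.047)) {
  scheme <- grading_scheme(3)
  out <- lapply(seeds, function(s) {
    s <- as.integer(s)
    antrum <- cohort_spec()
    corpus <- corpus_shift(antrum, norm = shift_norm, seed = 1000L + s)
    corpus$priors <- corpus_priors / sum(corpus_priors)
    pre_coh <- generate_cohort(antrum, n_pretrain, seed = s,
                               prefix = "antrum")
    tune_coh <- generate_cohort(corpus, n_tune, seed = 2000L + s,
                                prefix = "corpus")
    test_coh <- generate_cohort(corpus, n_test, seed = 3000L + s,
                                prefix = "corpustest")
    fit <- mil_grader(pre_coh$bags, pre_coh$labels$grade, scheme,
                      mil_config(n_classes = scheme$K, seed = s),
                      train_config(epochs = as.integer(epochs), seed = s))
    tuned <- fine_tune(fit, tune_coh$bags, tune_coh$labels$grade,
                       val_frac = 0.2)
    pre <- mean(predict(fit, test_coh$bags)$rank ==
                  test_coh$labels$grade)
    post <- mean(predict(tuned, test_coh$bags)$rank ==
                   test_coh$labels$grade)
    data.frame(seed = s, pre_accuracy = pre, post_accuracy = post,
               improved = post >= pre)
  })
  do.call(rbind, out)
}
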