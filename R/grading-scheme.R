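#' Grading scheme for one histological task
#'
#' The updated Sydney system grades four features of a gastric biopsy.
#' Inflammation and activity (tasks 1 and 2) are ternary because fully
#' normal mucosa is not encountered in routine biopsies; atrophy and
#' intestinal metaplasia (tasks 3 and 4) are quaternary with a true
#' "normal" grade.
#'
#' @param task Integer task id, 1--4: 1 inflammation, 2 activity,
#'   3 atrophy, 4 intestinal metaplasia.
#' @return An object of class `grading_scheme` with elements `task_id`,
#'   `task_name`, `classes` (ordered, least to most severe), `K` (class
#'   count) and `ranks` (`0:(K-1)`).
#' @examples
#' grading_scheme(3)
#' @export
grading_scheme <- function(task) {
  task <- as.integer(task)
  if (length(task) != 1L || is.na(task) || !task %in% 1:4)
    stop("'task' must be a single integer in 1..4", call. = FALSE)
  names4 <- c("inflammation", "activity", "atrophy", "intestinal metaplasia")
  classes <- if (task <= 2L) c("mild", "moderate", "severe")
             else c("normal", "mild", "moderate", "severe")
  structure(
    list(task_id = task, task_name = names4[task], classes = classes,
         K = length(classes), ranks = seq_along(classes) - 1L),
    class = "grading_scheme")
}

#' @export
print.grading_scheme <- function(x, ...) {
  cat(sprintf("Grading scheme: task %d (%s), %d classes\n",
              x$task_id, x$task_name, x$K))
  cat("  ranks:", paste(sprintf("%d=%s", x$ranks, x$classes),
                        collapse = ", "), "\n")
  invisible(x)
}

# coerce labels (factor of class names, character, or integer ranks) to
# integer ranks 0..K-1, validating against the scheme
as_ranks <- function(labels, scheme) {
  if (is.factor(labels)) labels <- as.character(labels)
  if (is.character(labels)) {
    idx <- match(labels, scheme$classes)
    if (anyNA(idx))
      stop("labels outside scheme: ",
           paste(unique(labels[is.na(idx)]), collapse = ", "), call. = FALSE)
    return(idx - 1L)
  }
  labels <- as.integer(labels)
  if (anyNA(labels) || any(labels < 0L | labels >= scheme$K))
    stop("label ranks must lie in 0..K-1", call. = FALSE)
  labels
}
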