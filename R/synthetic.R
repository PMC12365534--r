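#' Specification of a synthetic graded MIL cohort
#'
#' Desk-scale stand-in for a WSI cohort with known instance-level ground
#' truth.  Each bag mixes instances drawn from two Gaussian archetypes
#' in feature space -- background mucosa (mean 0) and lesion (mean
#' `separation` along a fixed unit direction), both isotropic with
#' scale `sigma` -- and the slide grade is determined by the lesion
#' infiltration ratio through ascending ratio bins, mirroring how
#' slide-level digital grades derive from the fraction of altered
#' tissue.  Grade priors default to the long-tailed antrum-atrophy
#' distribution (37.1 / 38.9 / 19.3 / 4.6 %) for quaternary schemes and
#' the activity-task distribution (61.8 / 21.1 / 17.1 %) for ternary
#' ones.
#'
#' @param n_features Feature dimension D.
#' @param K Number of grades (3 or 4).
#' @param separation Distance between archetype means.
#' @param sigma Isotropic archetype standard deviation.
#' @param bag_size Inclusive range of instances per bag.
#' @param bins Ratio-to-grade thresholds: `K - 1` strictly increasing
#'   cut points in (0, 1); grade g covers `[bins[g], bins[g+1])` with the
#'   top bin closed at 1.  Defaults to the visual-analog thirds, with a
#'   5% floor separating "normal" from "mild" in quaternary schemes.
#' @param priors Grade priors, length K, summing to 1.
#' @param archetype_seed Seed fixing the lesion direction (part of the
#'   spec, so two cohorts from the same spec share geometry).
#' @return An object of class `cohort_spec` with materialized
#'   `background_mean` and `lesion_mean` vectors.
#' @export
cohort_spec <- function(n_features = 1024L, K = 4L, separation = 1.5,
                        sigma = 1, bag_size = c(64L, 256L), bins = NULL,
                        priors = NULL, archetype_seed = 1L) {
  K <- as.integer(K)
  stopifnot(K %in% c(3L, 4L), n_features >= 1, separation >= 0, sigma > 0,
            length(bag_size) == 2L, bag_size[1] >= 1,
            bag_size[2] >= bag_size[1])
  if (is.null(bins))
    bins <- if (K == 4L) c(0.05, 1 / 3, 2 / 3) else c(1 / 3, 2 / 3)
  if (length(bins) != K - 1L || any(diff(c(0, bins, 1)) <= 0))
    stop("invalid spec: bins must be K-1 strictly increasing cut points in (0,1)",
         call. = FALSE)
  if (is.null(priors))
    priors <- if (K == 4L) c(0.371, 0.389, 0.193, 0.046)
              else c(0.618, 0.211, 0.171)
  priors <- priors / sum(priors)
  if (length(priors) != K)
    stop("invalid spec: priors must have length K", call. = FALSE)
  u <- withr::with_seed(archetype_seed, rnorm(n_features))
  u <- u / sqrt(sum(u^2))
  structure(
    list(n_features = as.integer(n_features), K = K,
         separation = separation, sigma = sigma,
         bag_size = as.integer(bag_size),
         bins = bins, priors = priors,
         background_mean = rep(0, n_features),
         lesion_mean = separation * u,
         archetype_seed = as.integer(archetype_seed)),
    class = "cohort_spec")
}

#' @export
print.cohort_spec <- function(x, ...) {
  cat(sprintf("cohort_spec: D = %d, K = %d, separation %.2f, sigma %.2f, bags %d-%d\n",
              x$n_features, x$K, x$separation, x$sigma,
              x$bag_size[1], x$bag_size[2]))
  cat("  ratio bins:", paste(signif(c(0, x$bins, 1), 3), collapse = " | "),
      "\n  priors:", paste(signif(x$priors, 3), collapse = " "), "\n")
  invisible(x)
}

#' Shift a cohort spec to simulate a corpus cohort
#'
#' Adds a fixed random offset of the given norm to both archetype means,
#' emulating the antrum-to-corpus histological domain shift while
#' leaving the grade-defining geometry (relative separation) unchanged.
#'
#' @param spec A [cohort_spec()].
#' @param norm Euclidean norm of the offset.
#' @param seed Seed fixing the offset direction.
#' @return A shifted `cohort_spec`.
#' @export
corpus_shift <- function(spec, norm = 0.5, seed = 100L) {
  stopifnot(inherits(spec, "cohort_spec"))
  o <- withr::with_seed(seed, rnorm(spec$n_features))
  o <- o / sqrt(sum(o^2)) * norm
  spec$background_mean <- spec$background_mean + o
  spec$lesion_mean <- spec$lesion_mean + o
  spec
}

# grade (0-based) for a realized ratio under the spec's bins
bin_grade <- function(spec, ratio) {
  findInterval(ratio, spec$bins)
}

#' Generate one synthetic bag of a given grade
#'
#' Draws a target infiltration ratio uniformly within the grade's bin,
#' realizes the nearest lesion count whose exact ratio `L / M` still
#' falls in the bin, and samples instances from the archetype Gaussians
#' in shuffled order.  Uses the current RNG state; seed the caller (or
#' use [generate_cohort()]) for reproducibility.
#'
#' @param spec A [cohort_spec()].
#' @param grade Target grade, `0..K-1`.
#' @param slide_id Identifier for the bag.
#' @return A `synthetic_bag` (also a [feature_bag()]) with extra fields
#'   `instance_labels` (1 = lesion), `ratio` (exact `L / M`), `grade`.
#' @export
generate_bag <- function(spec, grade, slide_id = "synthetic") {
  stopifnot(inherits(spec, "cohort_spec"))
  grade <- as.integer(grade)
  if (grade < 0L || grade >= spec$K)
    stop("grade must lie in 0..K-1", call. = FALSE)
  lo <- c(0, spec$bins)[grade + 1L]
  hi <- c(spec$bins, 1)[grade + 1L]
  M <- sample(seq(spec$bag_size[1], spec$bag_size[2]), 1L)
  valid <- which(vapply(0:M, function(l)
    bin_grade(spec, l / M) == grade, TRUE)) - 1L
  if (!length(valid))
    stop("invalid spec: empty ratio bin for grade ", grade,
         " at bag size ", M, call. = FALSE)
  target <- runif(1, lo, hi)
  L <- valid[which.min(abs(valid / M - target))]
  lab <- c(rep(1L, L), rep(0L, M - L))[sample.int(M)]
  X <- matrix(rnorm(M * spec$n_features, sd = spec$sigma), M,
              spec$n_features)
  X <- X + rep(spec$background_mean, each = M)
  if (L > 0) {
    delta <- spec$lesion_mean - spec$background_mean
    X[lab == 1L, ] <- X[lab == 1L, , drop = FALSE] +
      rep(delta, each = L)
  }
  bag <- feature_bag(X, slide_id = slide_id, backbone = "archetype",
                     magnification = 40)
  bag$instance_labels <- lab
  bag$ratio <- L / M
  bag$grade <- grade
  class(bag) <- c("synthetic_bag", class(bag))
  bag
}

#' Generate a graded synthetic cohort
#'
#' Pure function of `(spec, n, seed)`: grades are drawn from the spec's
#' priors and one bag is generated per slide.
#'
#' @param spec A [cohort_spec()].
#' @param n Number of slides.
#' @param seed RNG seed.
#' @param prefix Slide-id prefix.
#' @return List with `bags` (list of `synthetic_bag`) and `labels`
#'   (data frame `slide_id`, `grade`, `ratio`, `n_instances`).
#' @export
generate_cohort <- function(spec, n, seed = 1L, prefix = "synth") {
  stopifnot(inherits(spec, "cohort_spec"), n >= 1)
  withr::with_seed(seed, {
    grades <- sample(0:(spec$K - 1L), n, replace = TRUE,
                     prob = spec$priors)
    bags <- lapply(seq_len(n), function(i)
      generate_bag(spec, grades[i],
                   slide_id = sprintf("%s_%05d", prefix, i)))
  })
  labels <- data.frame(
    slide_id = vapply(bags, `[[`, "", "slide_id"),
    grade = vapply(bags, `[[`, 0L, "grade"),
    ratio = vapply(bags, `[[`, 0, "ratio"),
    n_instances = vapply(bags, function(b) nrow(b$features), 0L))
  list(bags = bags, labels = labels, spec = spec, seed = seed)
}

#' Generate a toy stained slide image
#'
#' Paints an H&E-like test image: white glass background, pink tissue
#' blobs, and optional purple lesion sub-regions, plus a ground-truth
#' region mask (0 background, 1 tissue, 2 lesion).  Used to exercise the
#' preprocessing chain end to end without real scans.
#'
#' @param width,height Image size in pixels (at least 512).
#' @param coverage Target tissue area fraction.
#' @param lesion_ratio Fraction of the tissue area to tint as lesion.
#' @param seed RNG seed.
#' @return List with `image` (H x W x 3 array in `[0, 1]`) and `mask`
#'   (H x W integer matrix).
#' @export
generate_toy_wsi <- function(width = 1024L, height = 1024L, coverage = 0.4,
                             lesion_ratio = 0.3, seed = 1L) {
  stopifnot(width >= 512L, height >= 512L,
            coverage > 0, coverage <= 0.9,
            lesion_ratio >= 0, lesion_ratio <= 1)
  withr::with_seed(seed, {
    xs <- matrix(rep(seq_len(width), each = height), height, width)
    ys <- matrix(rep(seq_len(height), width), height, width)
    tissue <- matrix(FALSE, height, width)
    r0 <- sqrt(coverage * width * height / pi) / 2
    guard <- 0L
    while (mean(tissue) < coverage && guard < 200L) {
      cx <- runif(1, 0.1, 0.9) * width
      cy <- runif(1, 0.1, 0.9) * height
      rx <- runif(1, 0.6, 1.4) * r0
      ry <- runif(1, 0.6, 1.4) * r0
      tissue <- tissue | (((xs - cx) / rx)^2 + ((ys - cy) / ry)^2 <= 1)
      guard <- guard + 1L
    }
    lesion <- matrix(FALSE, height, width)
    if (lesion_ratio > 0) {
      tix <- which(tissue)
      guard <- 0L
      rl <- r0 * sqrt(lesion_ratio) * 0.8
      while (sum(lesion) < lesion_ratio * sum(tissue) && guard < 200L) {
        ci <- tix[sample.int(length(tix), 1L)]
        cy <- (ci - 1L) %% height + 1L
        cx <- (ci - 1L) %/% height + 1L
        blob <- ((xs - cx)^2 + (ys - cy)^2 <= rl^2) & tissue
        lesion <- lesion | blob
        guard <- guard + 1L
      }
    }
    img <- array(1, c(height, width, 3))
    # eosin-pink tissue with mild texture
    tex <- matrix(rnorm(height * width, 0, 0.02), height, width)
    paint <- function(img, where, col) {
      for (k in 1:3) {
        ch <- img[, , k]
        ch[where] <- pmin(pmax(col[k] + tex[where], 0), 1)
        img[, , k] <- ch
      }
      img
    }
    img <- paint(img, tissue, c(0.93, 0.55, 0.70))
    if (any(lesion)) img <- paint(img, lesion, c(0.45, 0.25, 0.60))
    mask <- matrix(0L, height, width)
    mask[tissue] <- 1L
    mask[lesion] <- 2L
  })
  list(image = img, mask = mask)
}
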