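#' Patch-feature backbone contract
#'
#' A backbone maps one 256x256x3 RGB patch to a fixed-length feature
#' vector.  Pretrained encoders (ResNet50 and pathology foundation
#' models) plug in behind this contract; the package itself ships only
#' the deterministic [synthetic_backbone()] so that every test runs
#' without model downloads.
#'
#' @param name Backbone name.
#' @param dim Output feature dimension.
#' @param fn Function `(patch) -> numeric(dim)`.
#' @param deterministic Whether identical pixels always yield identical
#'   vectors.
#' @return An object of class `backbone_contract`.
#' @export
backbone_contract <- function(name, dim, fn, deterministic = TRUE) {
  stopifnot(is.function(fn), dim >= 1)
  structure(list(name = name, dim = as.integer(dim), fn = fn,
                 deterministic = isTRUE(deterministic)),
            class = "backbone_contract")
}

#' Content-hash test backbone
#'
#' Deterministic stand-in featurizer: the patch pixels are quantized to
#' 8 bits, hashed (FNV-1a) together with `seed_salt`, and the hash seeds
#' a standard-normal feature vector.  Any single-pixel change almost
#' surely changes the hash and therefore the whole vector, which makes
#' the backbone a useful sensitivity probe while staying fully
#' reproducible.
#'
#' @param patch RGB array with values in `[0, 1]`.
#' @param dim Feature dimension (1,024 matches the ResNet50 features the
#'   grading network is sized for).
#' @param seed_salt String mixed into the hash so distinct backbones
#'   decorrelate.
#' @return Numeric vector of length `dim`.
#' @export
synthetic_featurizer <- function(patch, dim = 1024L, seed_salt = "v1") {
  stopifnot(dim >= 1)
  q <- as.integer(round(pmin(pmax(as.numeric(patch), 0), 1) * 255))
  bytes <- c(as.raw(q %% 256L), charToRaw(seed_salt))
  h <- .fnv1a_cpp(bytes)
  seed <- as.integer(h %% 2147483646) + 1L
  withr::with_seed(seed, rnorm(dim))
}

#' @rdname synthetic_featurizer
#' @export
synthetic_backbone <- function(dim = 1024L, seed_salt = "v1") {
  backbone_contract(
    name = sprintf("synthetic-%d-%s", dim, seed_salt), dim = dim,
    fn = function(patch) synthetic_featurizer(patch, dim, seed_salt))
}

#' Feature bag: one slide as a matrix of patch features
#'
#' @param features M x D numeric matrix, one row per retained patch.
#' @param coords Data frame with base-level `x`, `y` per row, aligned to
#'   `features`.
#' @param slide_id Slide identifier.
#' @param backbone Backbone name the features came from.
#' @param magnification Working magnification the patches were read at.
#' @return An object of class `feature_bag`.
#' @export
feature_bag <- function(features, coords = NULL, slide_id = "slide",
                        backbone = "unknown", magnification = 40) {
  features <- as.matrix(features)
  if (nrow(features) < 1L)
    stop("empty bag: a feature bag needs at least one instance",
         call. = FALSE)
  if (!all(is.finite(features)))
    stop("feature bag contains non-finite values", call. = FALSE)
  if (is.null(coords))
    coords <- data.frame(x = rep(NA_real_, nrow(features)),
                         y = rep(NA_real_, nrow(features)))
  if (nrow(coords) != nrow(features))
    stop("coords rows must match feature rows", call. = FALSE)
  structure(list(slide_id = slide_id, features = unname(features),
                 coords = coords, backbone = backbone,
                 magnification = magnification),
            class = "feature_bag")
}

#' @export
print.feature_bag <- function(x, ...) {
  cat(sprintf("feature_bag '%s': %d instances x %d features (%s, %gx)\n",
              x$slide_id, nrow(x$features), ncol(x$features),
              x$backbone, x$magnification))
  invisible(x)
}

#' Extract features for every patch of a grid
#'
#' @param grid A `patch_grid` from [tile_foreground()].
#' @param slide The [slide_image()] the grid was tiled from.
#' @param backbone A [backbone_contract()].
#' @param batch_size Patches are processed in chunks of this size;
#'   batching never changes the result.
#' @return A [feature_bag()] whose rows follow grid order.
#' @export
extract_features <- function(grid, slide, backbone = synthetic_backbone(),
                             batch_size = 8L) {
  stopifnot(inherits(grid, "patch_grid"), inherits(slide, "slide_image"),
            inherits(backbone, "backbone_contract"))
  if (nrow(grid) == 0L)
    stop("empty bag: grid has no patches", call. = FALSE)
  f <- attr(grid, "factor"); px <- attr(grid, "patch_px")
  out <- matrix(NA_real_, nrow(grid), backbone$dim)
  for (start in seq(1L, nrow(grid), by = batch_size)) {
    idx <- start:min(nrow(grid), start + batch_size - 1L)
    for (i in idx) {
      patch <- read_patch(slide, grid$x[i], grid$y[i], px, f)
      v <- backbone$fn(patch)
      if (length(v) != backbone$dim)
        stop("contract violation: backbone returned length ", length(v),
             ", expected ", backbone$dim, call. = FALSE)
      out[i, ] <- v
    }
  }
  feature_bag(out, coords = grid[, c("x", "y")], slide_id = slide$slide_id,
              backbone = backbone$name,
              magnification = attr(grid, "magnification"))
}

BAG_SCHEMA <- "milgrade/feature_bags/1"

#' Persist feature bags
#'
#' Bags are stored in a single container file (RDS serialization of a
#' versioned list, one named group per slide holding `features`, `coords`
#' and metadata) with random access by `slide_id`.  The round trip is
#' bit-exact for the feature matrix.
#'
#' @param bags A `feature_bag` or list of them.
#' @param path Container file path.
#' @return `save_bags` returns `path` invisibly.  `load_bag` returns one
#'   `feature_bag`; `load_bags` returns the named list of all bags.
#' @export
save_bags <- function(bags, path) {
  if (inherits(bags, "feature_bag")) bags <- list(bags)
  stopifnot(all(vapply(bags, inherits, TRUE, "feature_bag")))
  names(bags) <- vapply(bags, `[[`, "", "slide_id")
  if (anyDuplicated(names(bags)))
    stop("duplicate slide_id in container", call. = FALSE)
  obj <- list(schema = BAG_SCHEMA, bags = bags)
  saveRDS(obj, path)
  invisible(path)
}

read_container <- function(path) {
  obj <- tryCatch(readRDS(path), error = function(e)
    stop("format error: cannot read bag container: ",
         conditionMessage(e), call. = FALSE))
  if (!is.list(obj) || !identical(obj$schema, BAG_SCHEMA))
    stop("format error: schema-version mismatch in bag container",
         call. = FALSE)
  obj
}

#' @rdname save_bags
#' @param slide_id Which bag to load.
#' @export
load_bag <- function(path, slide_id) {
  obj <- read_container(path)
  if (!slide_id %in% names(obj$bags))
    stop("slide_id '", slide_id, "' not in container", call. = FALSE)
  obj$bags[[slide_id]]
}

#' @rdname save_bags
#' @export
load_bags <- function(path) read_container(path)$bags
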