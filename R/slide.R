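#' Open a slide image
#'
#' Wraps a plain PNG/TIFF image (or an in-memory RGB array) as a
#' single-level slide at a declared objective magnification.  Gigapixel
#' pyramidal scans are normally served by a dedicated slide reader; the
#' same contract is kept here -- a pyramid whose base level is the full
#' resolution -- with one level, which is sufficient for fixture-scale
#' images and keeps all downstream coordinates in base-level pixels.
#'
#' @param x Path to a PNG or TIFF file, or an H x W x 3 numeric array in
#'   \code{[0, 1]}.
#' @param slide_id Identifier; defaults to the file name without extension.
#' @param magnification Nominal objective power of the base level.
#' @param mpp Microns per pixel at the base level (scanner metadata; the
#'   40x scans this pipeline targets are around 0.086 um/px).
#' @return An object of class `slide_image` with the pixel array, its
#'   dimensions, `mpp`, and `base_magnification`.
#' @export
slide_image <- function(x, slide_id = NULL, magnification = 40, mpp = 0.086) {
  if (is.character(x)) {
    if (is.null(slide_id))
      slide_id <- sub("\\.[^.]+$", "", basename(x))
    ext <- tolower(sub(".*\\.", "", x))
    img <- switch(ext,
      png = png::readPNG(x),
      tif = ,
      tiff = tiff::readTIFF(x),
      stop("unsupported slide format: .", ext, call. = FALSE))
  } else {
    img <- x
    if (is.null(slide_id)) slide_id <- "slide"
  }
  if (length(dim(img)) == 2L) img <- array(rep(img, 3L), c(dim(img), 3L))
  if (length(dim(img)) == 3L && dim(img)[3] >= 3L) img <- img[, , 1:3, drop = FALSE]
  else stop("slide must be an RGB image", call. = FALSE)
  if (mpp <= 0) stop("mpp must be positive", call. = FALSE)
  structure(
    list(slide_id = slide_id, pixels = img,
         width = dim(img)[2], height = dim(img)[1],
         mpp_x = mpp, mpp_y = mpp,
         base_magnification = magnification),
    class = "slide_image")
}

#' @export
print.slide_image <- function(x, ...) {
  cat(sprintf("slide_image '%s': %d x %d px, %gx base, %.3f um/px\n",
              x$slide_id, x$width, x$height, x$base_magnification, x$mpp_x))
  invisible(x)
}

#' Map a requested magnification to a pyramid level and scale factor
#'
#' @param slide A [slide_image()].
#' @param magnification Requested working magnification (10, 20 or 40).
#' @return List with `level` (0-based pyramid level; plain slides have a
#'   single level 0) and `factor`, the base-to-working downsample factor.
#' @export
select_working_level <- function(slide, magnification) {
  if (magnification > slide$base_magnification)
    stop("unsupported magnification: requested ", magnification,
         "x exceeds base ", slide$base_magnification, "x", call. = FALSE)
  f <- slide$base_magnification / magnification
  list(level = 0L, factor = f)
}

# block-mean downsample of an H x W (x C) array by integer factor f,
# cropping any remainder rows/cols
downsample_mean <- function(img, f) {
  f <- as.integer(f)
  if (f == 1L) return(img)
  d <- dim(img)
  h <- (d[1] %/% f) * f; w <- (d[2] %/% f) * f
  one_channel <- function(m) {
    m <- m[seq_len(h), seq_len(w), drop = FALSE]
    # average f x f blocks via two matrix reshapes
    m <- matrix(colMeans(matrix(m, nrow = f)), nrow = h %/% f, ncol = w)
    t(matrix(colMeans(matrix(t(m), nrow = f)), nrow = w %/% f, ncol = h %/% f))
  }
  if (length(d) == 2L) return(one_channel(img))
  out <- array(0, c(h %/% f, w %/% f, d[3]))
  for (k in seq_len(d[3])) out[, , k] <- one_channel(img[, , k])
  out
}

#' Segment tissue foreground
#'
#' Separates stained tissue from glass background on a thumbnail of the
#' slide.  Background pixels on an H&E scan are near-white and carry
#' almost no color saturation, so the mask thresholds the HSV saturation
#' channel: Otsu's threshold when the channel is informative, floored by
#' an absolute minimum saturation so uniformly blank slides yield an
#' empty mask.  A median filter and small-component removal clean up
#' isolated speckle.
#'
#' @param slide A [slide_image()].
#' @param downsample Integer thumbnail downsample factor relative to the
#'   base level.
#' @param sat_floor Minimum saturation a tissue pixel must carry.
#' @param median_radius Radius of the cleanup median filter (2 gives the
#'   usual 5x5 window); 0 disables filtering.
#' @param min_component Connected components smaller than this many
#'   thumbnail pixels are dropped; 0 disables.
#' @return An object of class `tissue_mask`: binary matrix `mask` (1 =
#'   tissue) plus its `downsample` factor.
#' @export
segment_tissue <- function(slide, downsample = 32L, sat_floor = 0.05,
                           median_radius = 2L, min_component = 64L) {
  stopifnot(inherits(slide, "slide_image"))
  downsample <- as.integer(downsample)
  th <- slide$height %/% downsample; tw <- slide$width %/% downsample
  if (th < 1L || tw < 1L)
    stop("invalid input: slide smaller than one thumbnail pixel", call. = FALSE)
  if (th < 16L || tw < 16L)
    stop("invalid input: thumbnail below 16x16; lower 'downsample'",
         call. = FALSE)
  thumb <- downsample_mean(slide$pixels, downsample)
  rgb <- rbind(as.vector(thumb[, , 1]), as.vector(thumb[, , 2]),
               as.vector(thumb[, , 3]))
  sat <- matrix(grDevices::rgb2hsv(rgb, maxColorValue = 1)[2L, ],
                nrow = dim(thumb)[1])
  thr <- sat_floor
  if (diff(range(sat)) > 1e-6)
    thr <- max(EBImage::otsu(sat, range = range(sat)), sat_floor)
  mask <- (sat >= thr) * 1
  if (median_radius > 0L && any(mask > 0) && !all(mask > 0))
    mask <- round(EBImage::medianFilter(mask, median_radius))
  if (min_component > 0L && any(mask > 0)) {
    lab <- EBImage::bwlabel(mask)
    sizes <- tabulate(lab[lab > 0])
    drop <- which(sizes < min_component)
    if (length(drop)) mask[lab %in% drop] <- 0
  }
  structure(list(mask = mask, downsample = downsample),
            class = "tissue_mask")
}

#' @export
print.tissue_mask <- function(x, ...) {
  cat(sprintf("tissue_mask: %d x %d at 1/%d, tissue fraction %.3f\n",
              nrow(x$mask), ncol(x$mask), x$downsample, mean(x$mask)))
  invisible(x)
}

#' Tile foreground tissue into a non-overlapping patch grid
#'
#' Lays a regular lattice of stride `patch_px` over the working level and
#' keeps patches whose tissue fraction under `mask` reaches
#' `min_foreground`.  Coordinates are stored 0-based, half-open, in
#' base-level pixels, so a patch occupies `[x, x + patch_px * factor)`
#' regardless of the working magnification.
#'
#' @param slide A [slide_image()].
#' @param mask A [segment_tissue()] result (or `NULL` to treat the whole
#'   slide as foreground).
#' @param magnification Working magnification (10, 20 or 40).
#' @param min_foreground Minimum tissue fraction for a patch to be kept.
#' @param patch_px Patch edge in working-level pixels (256).
#' @return A `patch_grid`: data frame with columns `slide_id`, `x`, `y`
#'   (base-level), `foreground_fraction`, and attributes `magnification`,
#'   `factor`, `patch_px`.
#' @export
tile_foreground <- function(slide, mask = NULL, magnification = 40,
                            min_foreground = 0.5, patch_px = 256L) {
  stopifnot(inherits(slide, "slide_image"))
  lv <- select_working_level(slide, magnification)
  f <- lv$factor
  wl <- slide$width %/% f; hl <- slide$height %/% f
  nx <- wl %/% patch_px; ny <- hl %/% patch_px
  rows <- list()
  if (nx >= 1L && ny >= 1L) {
    ds <- if (is.null(mask)) NULL else mask$downsample
    for (j in seq_len(ny) - 1L) {
      for (i in seq_len(nx) - 1L) {
        x0 <- i * patch_px * f; y0 <- j * patch_px * f
        if (is.null(mask)) fg <- 1
        else {
          c0 <- floor(x0 / ds) + 1L
          c1 <- min(ncol(mask$mask), ceiling((x0 + patch_px * f) / ds))
          r0 <- floor(y0 / ds) + 1L
          r1 <- min(nrow(mask$mask), ceiling((y0 + patch_px * f) / ds))
          fg <- mean(mask$mask[r0:r1, c0:c1])
        }
        if (fg >= min_foreground)
          rows[[length(rows) + 1L]] <- c(x0, y0, fg)
      }
    }
  }
  if (length(rows)) {
    m <- do.call(rbind, rows)
    grid <- data.frame(slide_id = slide$slide_id, x = m[, 1], y = m[, 2],
                       foreground_fraction = m[, 3])
  } else {
    grid <- data.frame(slide_id = character(), x = numeric(),
                       y = numeric(), foreground_fraction = numeric())
  }
  structure(grid, magnification = magnification, factor = f,
            patch_px = patch_px, class = c("patch_grid", "data.frame"))
}

#' Write / read a patch grid as CSV with a JSON sidecar
#'
#' The sidecar records the tiling configuration and an MD5 checksum of
#' the CSV so that feature bags can verify they are aligned with the grid
#' they were extracted from.  Serialization is deterministic: identical
#' inputs produce byte-identical files.
#'
#' @param grid A `patch_grid`.
#' @param path CSV path; the sidecar is written next to it as
#'   `<path>.json`.
#' @return `write_grid` returns `path` invisibly; `read_grid` returns the
#'   `patch_grid`.
#' @export
write_grid <- function(grid, path) {
  stopifnot(inherits(grid, "patch_grid"))
  df <- as.data.frame(grid)
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  meta <- list(schema = "milgrade/patch_grid/1",
               magnification = attr(grid, "magnification"),
               factor = attr(grid, "factor"),
               patch_px = attr(grid, "patch_px"),
               n_patches = nrow(df),
               csv_md5 = unname(tools::md5sum(path)))
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_grid
#' @export
read_grid <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"))
  if (!identical(meta$schema, "milgrade/patch_grid/1"))
    stop("format error: not a patch_grid sidecar", call. = FALSE)
  if (!identical(unname(tools::md5sum(path)), meta$csv_md5))
    stop("format error: grid CSV checksum mismatch", call. = FALSE)
  df <- read.csv(path, stringsAsFactors = FALSE)
  structure(df, magnification = meta$magnification, factor = meta$factor,
            patch_px = meta$patch_px, class = c("patch_grid", "data.frame"))
}

# extract one patch (patch_px x patch_px x 3 at the working level) from the
# base-level pixel array, block-averaging when factor > 1
read_patch <- function(slide, x, y, patch_px = 256L, factor = 1) {
  f <- as.integer(factor)
  sub <- slide$pixels[(y + 1):(y + patch_px * f),
                      (x + 1):(x + patch_px * f), , drop = FALSE]
  downsample_mean(sub, f)
}
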