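uniform_slide <- function(col, w = 512, h = 512, mag = 40) {
  img <- array(rep(col, each = h * w), c(h, w, 3))
  slide_image(img, slide_id = "fix", magnification = mag)
}

test_that("working-level selection maps magnifications deterministically", {
  s <- uniform_slide(c(1, 1, 1))
  expect_equal(select_working_level(s, 40), list(level = 0L, factor = 1))
  expect_equal(select_working_level(s, 20)$factor, 2)
  expect_equal(select_working_level(s, 10)$factor, 4)
  expect_error(select_working_level(s, 80), "unsupported magnification")
})

test_that("blank glass yields an empty mask and saturated tissue a full mask", {
  white <- segment_tissue(uniform_slide(c(1, 1, 1)), downsample = 16)
  expect_true(all(white$mask == 0))
  pink <- segment_tissue(uniform_slide(c(0.93, 0.55, 0.70)), downsample = 16)
  expect_true(all(pink$mask == 1))
  expect_error(segment_tissue(uniform_slide(c(1, 1, 1), 64, 64)),
               "invalid input")
})

test_that("a pink block on glass matches the per-pixel saturation-threshold oracle", {
  img <- array(1, c(512, 512, 3))
  img[129:384, 129:384, 1] <- 0.93
  img[129:384, 129:384, 2] <- 0.55
  img[129:384, 129:384, 3] <- 0.70
  s <- slide_image(img, magnification = 40)
  ds <- 16L
  m <- segment_tissue(s, downsample = ds, median_radius = 0,
                      min_component = 0)
  # oracle: block-mean thumbnail, saturation, any threshold between the two
  # modes gives the same binary mask
  sat <- matrix(NA_real_, 512 / ds, 512 / ds)
  for (i in seq_len(nrow(sat))) for (j in seq_len(ncol(sat))) {
    px <- c(mean(img[(i - 1) * ds + 1:ds, (j - 1) * ds + 1:ds, 1]),
            mean(img[(i - 1) * ds + 1:ds, (j - 1) * ds + 1:ds, 2]),
            mean(img[(i - 1) * ds + 1:ds, (j - 1) * ds + 1:ds, 3]))
    sat[i, j] <- (max(px) - min(px)) / max(px)
  }
  thr <- mean(range(sat))
  expect_identical(m$mask == 1, sat >= thr)
  expect_equal(mean(m$mask), 0.25, tolerance = 1e-12)
  # default cleanup keeps the aligned block's area close to a quarter
  m2 <- segment_tissue(s, downsample = ds)
  expect_equal(mean(m2$mask), 0.25, tolerance = 0.05)
})

test_that("tiling a full-foreground slide yields the closed-form lattice", {
  img <- array(rep(c(0.9, 0.4, 0.6), each = 512 * 1024), c(512, 1024, 3))
  s <- slide_image(img, magnification = 40)
  g <- tile_foreground(s, mask = NULL, magnification = 40)
  expect_equal(nrow(g), 8)                      # floor(1024/256)*floor(512/256)
  expect_setequal(unique(g$x), c(0, 256, 512, 768))
  expect_setequal(unique(g$y), c(0, 256))
  # closed form on assorted sizes
  for (wh in list(c(768, 256), c(300, 300), c(1024, 768))) {
    im <- array(0.5, c(wh[2], wh[1], 3))
    gg <- tile_foreground(slide_image(im), NULL, 40)
    expect_equal(nrow(gg), (wh[1] %/% 256) * (wh[2] %/% 256))
  }
})

test_that("tiling respects the mask, matches lattice enumeration and never overlaps", {
  img <- array(1, c(256, 1024, 3))
  img[, 1:512, 1] <- 0.93; img[, 1:512, 2] <- 0.55; img[, 1:512, 3] <- 0.70
  s <- slide_image(img, magnification = 40)
  mask <- segment_tissue(s, downsample = 16)
  g <- tile_foreground(s, mask, 40, min_foreground = 0.5)
  expect_setequal(g$x, c(0, 256))
  # exhaustive enumeration oracle with per-cell mask counting
  oracle <- list()
  for (x0 in seq(0, 1024 - 256, by = 256)) {
    cells <- mask$mask[, (x0 / 16 + 1):((x0 + 256) / 16)]
    if (mean(cells) >= 0.5) oracle[[length(oracle) + 1]] <- x0
  }
  expect_equal(sort(g$x), sort(unlist(oracle)))
  # no two patch rectangles intersect
  if (nrow(g) > 1) {
    sz <- attr(g, "patch_px") * attr(g, "factor")
    for (i in 1:(nrow(g) - 1)) for (j in (i + 1):nrow(g)) {
      overl <- g$x[i] < g$x[j] + sz && g$x[j] < g$x[i] + sz &&
               g$y[i] < g$y[j] + sz && g$y[j] < g$y[i] + sz
      expect_false(overl)
    }
  }
  # all-background slide gives an empty grid
  g0 <- tile_foreground(uniform_slide(c(1, 1, 1)),
                        segment_tissue(uniform_slide(c(1, 1, 1))), 40)
  expect_equal(nrow(g0), 0)
})

test_that("raising min_foreground never increases the patch count", {
  toy <- generate_toy_wsi(1024, 768, coverage = 0.35, lesion_ratio = 0,
                          seed = 4)
  s <- slide_image(toy$image, magnification = 40)
  mask <- segment_tissue(s)
  counts <- vapply(c(0.1, 0.3, 0.5, 0.7, 0.9), function(mf)
    nrow(tile_foreground(s, mask, 40, min_foreground = mf)), 0)
  expect_true(all(diff(counts) <= 0))
})

test_that("patch-grid serialization is deterministic and round-trips", {
  toy <- generate_toy_wsi(768, 512, coverage = 0.4, seed = 2)
  s <- slide_image(toy$image, slide_id = "toy", magnification = 40)
  g <- tile_foreground(s, segment_tissue(s), 40)
  f1 <- tempfile(fileext = ".csv"); f2 <- tempfile(fileext = ".csv")
  write_grid(g, f1); write_grid(g, f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
  g2 <- read_grid(f1)
  expect_equal(as.data.frame(g), as.data.frame(g2), tolerance = 1e-12)
  expect_equal(attr(g2, "factor"), attr(g, "factor"))
  # checksum mismatch is a format error
  writeLines("slide_id,x,y,foreground_fraction", f1)
  expect_error(read_grid(f1), "format error")
})
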