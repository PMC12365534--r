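#' Render a whole-slide attention heatmap
#'
#' Colors every foreground patch -- not a top-k subset -- by its
#' attention weight, min-max normalized per slide, on a continuous pale
#' blue to dark red ramp (rising color = heightened model attention),
#' alpha-blended over a slide thumbnail.  Constant-attention slides map
#' to the ramp midpoint.  Normalization is per-slide because softmax
#' attention scales with bag size, so absolute weights are not
#' comparable across slides.
#'
#' @param attn An `attention_map` aligned to `grid`.
#' @param grid The `patch_grid` the bag was extracted from.
#' @param slide The [slide_image()].
#' @param downsample Thumbnail downsample factor.
#' @param alpha Overlay opacity over tissue patches.
#' @param colors Color-ramp anchors, low to high attention.
#' @param label Caption recorded with the render (e.g., the task name).
#' @return An object of class `heatmap_render`: `thumbnail`, `overlay`
#'   (RGBA), `composite` (RGB), `bounds` (attention min/max),
#'   `normalized` (per-patch values in `[0, 1]`), `colors`, `alpha`,
#'   `label`, `downsample`.
#' @export
render_heatmap <- function(attn, grid, slide, downsample = 32L,
                           alpha = 0.5,
                           colors = c("#ADD8E6", "#F2C4AE", "#E06D5E",
                                      "#8B0000"),
                           label = "attention") {
  stopifnot(inherits(attn, "attention_map"), inherits(grid, "patch_grid"),
            inherits(slide, "slide_image"))
  M <- nrow(grid)
  if (length(attn$weights) != M)
    stop("contract violation: attention length ", length(attn$weights),
         " != grid size ", M, call. = FALSE)
  a <- attn$weights
  lo <- min(a); hi <- max(a)
  norm <- if (hi - lo < .Machine$double.eps) rep(0.5, M)
          else (a - lo) / (hi - lo)
  thumb <- downsample_mean(slide$pixels, downsample)
  th <- dim(thumb)[1]; tw <- dim(thumb)[2]
  ramp <- grDevices::colorRamp(colors)
  overlay <- array(0, c(th, tw, 4))
  block <- attr(grid, "patch_px") * attr(grid, "factor") / downsample
  for (i in seq_len(M)) {
    col <- ramp(norm[i]) / 255
    r0 <- floor(grid$y[i] / downsample) + 1L
    c0 <- floor(grid$x[i] / downsample) + 1L
    r1 <- min(th, ceiling(grid$y[i] / downsample + block))
    c1 <- min(tw, ceiling(grid$x[i] / downsample + block))
    if (r0 > th || c0 > tw) next
    overlay[r0:r1, c0:c1, 1] <- col[1]
    overlay[r0:r1, c0:c1, 2] <- col[2]
    overlay[r0:r1, c0:c1, 3] <- col[3]
    overlay[r0:r1, c0:c1, 4] <- alpha
  }
  composite <- thumb
  av <- overlay[, , 4]
  for (k in 1:3)
    composite[, , k] <- overlay[, , k] * av + thumb[, , k] * (1 - av)
  structure(
    list(thumbnail = thumb, overlay = overlay, composite = composite,
         bounds = c(min = lo, max = hi), normalized = norm,
         colors = colors, alpha = alpha, label = label,
         downsample = downsample, n_patches = M),
    class = "heatmap_render")
}

#' @export
print.heatmap_render <- function(x, ...) {
  cat(sprintf("heatmap_render '%s': %d patches, attention [%.3g, %.3g], 1/%d thumbnail\n",
              x$label, x$n_patches, x$bounds[1], x$bounds[2],
              x$downsample))
  invisible(x)
}

#' Export a heatmap render as PNG
#'
#' Appends a horizontal colorbar legend band under the composite and
#' writes a PNG whose text metadata carries the label and the color
#' semantics.  Output bytes are a deterministic function of the render.
#'
#' @param render A [render_heatmap()] result.
#' @param path Output PNG path.
#' @return `path`, invisibly.
#' @export
export_heatmap <- function(render, path) {
  stopifnot(inherits(render, "heatmap_render"))
  comp <- render$composite
  tw <- dim(comp)[2]
  bar_h <- max(8L, dim(comp)[1] %/% 20L)
  ramp <- grDevices::colorRamp(render$colors)
  bar <- array(1, c(bar_h + 4L, tw, 3))
  cols <- ramp(seq(0, 1, length.out = tw)) / 255
  for (k in 1:3)
    bar[3:(bar_h + 2L), , k] <- matrix(cols[, k], bar_h, tw, byrow = TRUE)
  out <- array(0, c(dim(comp)[1] + bar_h + 4L, tw, 3))
  out[seq_len(dim(comp)[1]), , ] <- comp
  out[dim(comp)[1] + seq_len(bar_h + 4L), , ] <- bar
  ok <- tryCatch({
    png::writePNG(out, path,
                  text = c(title = render$label,
                           legend = "attention: pale blue (low) to dark red (high)",
                           software = "milgrade"))
    TRUE
  }, error = function(e)
    stop("I/O error writing heatmap: ", conditionMessage(e), call. = FALSE))
  invisible(path)
}

#' Instance-level localization of attention
#'
#' Measures how well attention separates lesion from background
#' instances when ground-truth instance labels are known (synthetic
#' cohorts): pooled ROC-AUC of per-bag min-max normalized attention
#' against the instance labels, plus the mean attention gap.  Min-max
#' normalization puts bags of different sizes on a common scale while
#' preserving the within-bag ranking that the heatmap displays.
#'
#' @param attention List of `attention_map`s (or numeric vectors).
#' @param instance_labels List of 0/1 vectors aligned to the maps.
#' @return List with `auc`, `mean_lesion`, `mean_background` (of
#'   normalized attention), `n_instances`.
#' @export
attention_localization <- function(attention, instance_labels) {
  stopifnot(length(attention) == length(instance_labels))
  norm1 <- function(a) {
    a <- if (inherits(a, "attention_map")) a$weights else as.numeric(a)
    lo <- min(a); hi <- max(a)
    if (hi - lo < .Machine$double.eps) rep(0.5, length(a))
    else (a - lo) / (hi - lo)
  }
  sc <- unlist(lapply(attention, norm1))
  lab <- unlist(instance_labels)
  stopifnot(length(sc) == length(lab))
  list(auc = binary_auc(as.integer(lab), sc),
       mean_lesion = mean(sc[lab == 1]),
       mean_background = mean(sc[lab == 0]),
       n_instances = length(lab))
}
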