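#' Estimate an H&E stain basis (Macenko method)
#'
#' Converts the patch to optical density (Beer--Lambert,
#' \eqn{OD = -\log(I/I_0)}), keeps pixels with appreciable OD in every
#' channel, projects the OD point cloud onto the plane of its two leading
#' eigenvectors, and takes the directions at the extreme percentiles of
#' the angular distribution as the hematoxylin and eosin stain vectors.
#' Hematoxylin is identified as the vector with the larger red-channel
#' OD.  Per-stain concentration scales are the 99th percentile of the
#' least-squares concentrations, used for scale matching during
#' normalization.
#'
#' @param patch H x W x 3 RGB array in `[0, 1]`, or a `slide_image`.
#' @param beta OD threshold below which a pixel is considered unstained
#'   (0.15, the method's canonical constant).
#' @param alpha Angular percentile (1 gives the 1st/99th percentiles).
#' @param source_id Optional identifier recorded in the basis.
#' @return An object of class `stain_basis`: `M` (3 x 2 unit-norm OD
#'   matrix, columns H then E), `max_conc` (length-2 99th-percentile
#'   concentrations), `source_id`.
#' @export
fit_stain_basis <- function(patch, beta = 0.15, alpha = 1,
                            source_id = "target") {
  if (inherits(patch, "slide_image")) patch <- patch$pixels
  od <- od_from_rgb(patch)
  keep <- rowSums(od > beta) == 3L
  if (sum(keep) < 10L)
    stop("degenerate stain: patch has no optical-density signal",
         call. = FALSE)
  odh <- od[keep, , drop = FALSE]
  ev <- eigen(cov(odh), symmetric = TRUE)
  V <- ev$vectors[, 1:2, drop = FALSE]
  # orient eigenvectors into the positive OD octant
  for (k in 1:2) if (sum(V[, k]) < 0) V[, k] <- -V[, k]
  proj <- odh %*% V
  phi <- atan2(proj[, 2], proj[, 1])
  qs <- quantile(phi, c(alpha, 100 - alpha) / 100, names = FALSE)
  v1 <- V %*% c(cos(qs[1]), sin(qs[1]))
  v2 <- V %*% c(cos(qs[2]), sin(qs[2]))
  M <- if (v1[1] > v2[1]) cbind(v1, v2) else cbind(v2, v1)
  M[M < 0] <- 0
  M <- sweep(M, 2, sqrt(colSums(M^2)), "/")
  conc <- stain_concentrations(od, M)
  structure(
    list(M = unname(M),
         max_conc = apply(conc, 2, quantile, probs = 0.99, names = FALSE),
         source_id = source_id),
    class = "stain_basis")
}

#' @export
print.stain_basis <- function(x, ...) {
  cat(sprintf("stain_basis '%s'\n", x$source_id))
  m <- round(x$M, 3); dimnames(m) <- list(c("R", "G", "B"), c("H", "E"))
  print(m)
  cat("99th-pct concentrations:", signif(x$max_conc, 4), "\n")
  invisible(x)
}

#' Normalize a patch to a target stain basis (Macenko)
#'
#' Decomposes the patch's optical density into stain concentrations under
#' the `source` basis (unconstrained least squares, clipped at zero),
#' rescales each stain so its 99th-percentile concentration matches the
#' target's, and reconstructs RGB under the `target` basis.
#'
#' @param patch H x W x 3 RGB array in `[0, 1]`.
#' @param source `stain_basis` fitted on the patch (or its slide).
#' @param target `stain_basis` of the reference image.
#' @return RGB array of the same shape, values clipped to `[0, 1]`.
#' @export
macenko_normalize <- function(patch, source, target) {
  stopifnot(inherits(source, "stain_basis"), inherits(target, "stain_basis"))
  d <- dim(patch)
  if (length(d) != 3L || d[3] != 3L)
    stop("invalid input: patch must be H x W x 3", call. = FALSE)
  od <- od_from_rgb(patch)
  conc <- stain_concentrations(od, source$M)
  scale <- target$max_conc / pmax(source$max_conc, 1e-8)
  conc <- sweep(conc, 2, scale, "*")
  od_new <- conc %*% t(target$M)
  out <- exp(-od_new)
  out[out > 1] <- 1; out[out < 0] <- 0
  array(out, d)
}

# Beer-Lambert optical density of an RGB array, N x 3, I0 = 1 with an
# 8-bit floor so pure black stays finite
od_from_rgb <- function(patch) {
  n <- prod(dim(patch)[1:2])
  od <- -log(pmax(matrix(patch, n, 3), 1 / 255))
  od
}

# Nonnegative stain concentrations.  For the two-column H&E system the
# NNLS solution has a closed form: take the unconstrained least squares
# solution; if a coefficient is negative, the optimum lies on that
# boundary, so clamp it and refit the other stain alone.
stain_concentrations <- function(od, M) {
  conc <- t(qr.solve(M, t(od)))
  bad1 <- conc[, 1] < 0
  bad2 <- conc[, 2] < 0
  if (any(bad1)) {
    conc[bad1, 1] <- 0
    conc[bad1, 2] <- pmax(0, od[bad1, , drop = FALSE] %*% M[, 2] /
                            sum(M[, 2]^2))
  }
  if (any(bad2)) {
    conc[bad2, 2] <- 0
    conc[bad2, 1] <- pmax(0, od[bad2, , drop = FALSE] %*% M[, 1] /
                            sum(M[, 1]^2))
  }
  conc
}
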