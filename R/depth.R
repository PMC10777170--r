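# Feature radiological-depth estimation from the focal-depth map: the depth
# plane of maximal sharpness at a high-gradient pixel is interpreted as the
# radiological depth of the local feature.

#' Pixel-index rectangle around a cube's bottom edge
#'
#' The standard depth-estimation region: `n_t` x `n_v` pixels centred on the
#' midpoint of the cube's bottom edge.
#'
#' @param grid an [image_grid()]
#' @param phantom a [cube_phantom()]
#' @param cube cube index
#' @param n_t,n_v region size in pixels (horizontal, vertical)
#' @return list with integer index vectors `it`, `iv`
#' @export
cube_bottom_edge_roi <- function(grid, phantom, cube, n_t = 20, n_v = 4) {
  edge <- cube_edges(phantom, cube)[[3]]  # bottom edge
  it0 <- which.min(abs(grid$t_centers - edge$p0[1]))
  iv0 <- which.min(abs(grid$v_centers - edge$p0[2]))
  it <- (it0 - n_t %/% 2 + 1):(it0 + n_t %/% 2)
  iv <- (iv0 - n_v %/% 2 + 1):(iv0 + n_v %/% 2)
  list(it = it[it >= 1 & it <= grid$nt], iv = iv[iv >= 1 & iv <= grid$nv])
}

#' Feature depth estimate from a region of the focal-depth map
#'
#' Collects the per-pixel focal depths of the valid pixels in a rectangular
#' region and summarizes their distribution. The median is the headline depth
#' estimator.
#'
#' @param result a `focus_result` from [focus_stack()]
#' @param roi pixel rectangle: list with index vectors `it`, `iv` (e.g. from
#'   [cube_bottom_edge_roi()])
#' @return a `depth_estimate`: list with `median_depth` (mm), `iqr` (mm),
#'   `depths` (the per-pixel values), `roi`, and `profile` (per-plane mean and
#'   sd of the region's sharpness, for diagnostics)
#' @export
roi_depth_estimate <- function(result, roi) {
  stopifnot(inherits(result, "focus_result"),
            is.list(roi), length(roi$it) >= 1, length(roi$iv) >= 1,
            all(roi$it >= 1), all(roi$it <= nrow(result$focal_depth_map)),
            all(roi$iv >= 1), all(roi$iv <= ncol(result$focal_depth_map)))
  d <- result$focal_depth_map[roi$it, roi$iv]
  d <- d[!is.na(d)]
  if (!length(d)) stop("ROI contains no valid focal-depth pixel")
  structure(list(
    median_depth = median(d),
    iqr = unname(diff(quantile(d, c(0.25, 0.75)))),
    depths = as.numeric(d),
    roi = roi,
    profile = laplacian_depth_profile(result$sharpness, roi)
  ), class = "depth_estimate")
}

#' @export
print.depth_estimate <- function(x, ...) {
  cat(sprintf("depth_estimate: median %.1f mm (IQR %.1f mm, %d pixels)\n",
              x$median_depth, x$iqr, length(x$depths)))
  invisible(x)
}

#' Mean sharpness-versus-depth profile of a region
#'
#' Per-plane mean and standard deviation of the |Laplacian| sharpness over
#' the region's pixels.
#'
#' @param s a `sharpness_stack`
#' @param roi pixel rectangle: list with index vectors `it`, `iv`
#' @return data.frame with `depth` (mm), `mean`, `sd`
#' @export
laplacian_depth_profile <- function(s, roi) {
  stopifnot(inherits(s, "sharpness_stack"),
            length(roi$it) >= 1, length(roi$iv) >= 1)
  vals <- s$values[roi$it, roi$iv, , drop = FALSE]
  nd <- length(s$depths)
  m <- numeric(nd); sdev <- numeric(nd)
  for (n in seq_len(nd)) {
    x <- vals[, , n]
    x <- x[!is.na(x)]
    m[n] <- if (length(x)) mean(x) else NA_real_
    sdev[n] <- if (length(x) > 1) sd(x) else NA_real_
  }
  data.frame(depth = s$depths, mean = m, sd = sdev)
}
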