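# Focus stacking: collapse a DDB depth stack into a single image by selecting,
# per pixel, the depth plane where the absolute value of the (Gaussian
# pre-blurred) Laplacian-convolved image is largest.

#' 5x5 Gaussian kernel
#' @param sigma kernel standard deviation in pixels
#' @return a normalized 5x5 matrix (sums to 1)
#' @export
gaussian_kernel <- function(sigma = 1) {
  stopifnot(sigma > 0)
  w <- exp(-(-2:2)^2 / (2 * sigma^2))
  k <- outer(w, w)
  k / sum(k)
}

#' 5x5 Laplacian kernel
#'
#' Fixed zero-sum Laplacian-of-Gaussian-style kernel used as the sharpness
#' operator. Zero-sum is asserted so that constant regions map to zero.
#' @return a 5x5 matrix
#' @export
laplacian_kernel <- function() {
  k <- matrix(c(0, 0, 1, 0, 0,
                0, 1, 2, 1, 0,
                1, 2, -16, 2, 1,
                0, 1, 2, 1, 0,
                0, 0, 1, 0, 0), 5, 5, byrow = TRUE)
  stopifnot(sum(k) == 0)
  k
}

# Direct 2D convolution with reflect padding (edge-inclusive mirror:
# d c b a | a b c d). Taps are accumulated in a fixed (ki outer, kj inner)
# order; NA pixels propagate.
convolve2_reflect <- function(img, kernel) {
  nt <- nrow(img); nv <- ncol(img)
  kh <- nrow(kernel); kw <- ncol(kernel)
  if (nt < kh || nv < kw) stop("image smaller than the convolution kernel")
  ht <- (kh - 1L) %/% 2L; hv <- (kw - 1L) %/% 2L
  reflect_idx <- function(n, h) {
    i <- c(h:1, 1:n, n:(n - h + 1L))
    i
  }
  ri <- reflect_idx(nt, ht); ci <- reflect_idx(nv, hv)
  pad <- img[ri, ci, drop = FALSE]
  out <- matrix(0, nt, nv)
  for (ki in seq_len(kh)) {
    for (kj in seq_len(kw)) {
      out <- out + kernel[ki, kj] *
        pad[(ki - 1L) + seq_len(nt), (kj - 1L) + seq_len(nv), drop = FALSE]
    }
  }
  out
}

#' Gaussian pre-blur of a WET image
#'
#' 5x5 normalized Gaussian convolution with reflect-padded boundaries.
#' Invalid (`NA`) pixels are excluded through mask-weighted normalization:
#' the blurred value is the kernel-weighted mean of the valid neighbours.
#' Pixels whose whole neighbourhood is invalid stay `NA`.
#'
#' @param image nt x nv matrix, `NA` marking invalid pixels
#' @param sigma Gaussian sigma in pixels
#' @return blurred matrix
#' @export
gaussian_blur <- function(image, sigma = 1) {
  k <- gaussian_kernel(sigma)
  mask <- !is.na(image)
  img0 <- image
  img0[!mask] <- 0
  num <- convolve2_reflect(img0, k)
  den <- convolve2_reflect(mask * 1.0, k)
  out <- num / den
  out[den == 0] <- NA_real_
  out
}

#' Laplacian convolution of an image
#'
#' Applies the fixed 5x5 zero-sum Laplacian kernel with reflect padding.
#' Constant images map to zero everywhere; affine ramps map to zero in the
#' interior. `NA` pixels propagate through the kernel footprint.
#'
#' @param image nt x nv matrix
#' @return convolved matrix
#' @export
laplacian <- function(image) {
  convolve2_reflect(image, laplacian_kernel())
}

#' Per-plane sharpness of a DDB stack
#'
#' For each plane, the absolute value of the Laplacian of the Gaussian
#' pre-blurred image.
#'
#' @param stack a `ddb_stack`
#' @param sigma Gaussian pre-blur sigma in pixels
#' @return a `sharpness_stack`: list with `values` (nt x nv x n array, `NA`
#'   for invalid), `depths`, `grid`
#' @export
sharpness <- function(stack, sigma = 1) {
  stopifnot(inherits(stack, "ddb_stack"))
  nd <- length(stack$depths)
  vals <- array(NA_real_, dim = dim(stack$images))
  for (n in seq_len(nd)) {
    vals[, , n] <- abs(laplacian(gaussian_blur(stack$images[, , n], sigma)))
  }
  structure(list(values = vals, depths = stack$depths, grid = stack$grid),
            class = "sharpness_stack")
}

# Savitzky-Golay smoothing operator: per output plane n, the contiguous
# support indices and weights, with polynomial-fit endpoint handling.
sg_operator <- function(nd, window, polyorder) {
  h <- (window - 1L) %/% 2L
  FF <- signal::sgolay(p = polyorder, n = window)
  lapply(seq_len(nd), function(n) {
    if (n <= h) list(idx = 1:window, w = FF[n, ])
    else if (n > nd - h) list(idx = (nd - window + 1L):nd,
                              w = FF[window - (nd - n), ])
    else list(idx = (n - h):(n + h), w = FF[h + 1L, ])
  })
}

#' Savitzky-Golay smoothing of per-pixel sharpness depth profiles
#'
#' Smooths each pixel's sharpness-vs-depth profile with a Savitzky-Golay
#' filter (polynomial least-squares fits over a moving window; endpoint
#' samples use the off-centre fits). The output is clipped at zero. Invalid
#' (`NA`) samples are treated as zero sharpness during smoothing and remain
#' invalid in the output. `window = 1` disables smoothing.
#'
#' @param s a `sharpness_stack`
#' @param window odd window length in planes, `> polyorder` and at most the
#'   number of planes
#' @param polyorder polynomial order
#' @return a smoothed `sharpness_stack`
#' @export
smooth_depth_profiles <- function(s, window = 11, polyorder = 3) {
  stopifnot(inherits(s, "sharpness_stack"))
  if (window == 1) return(s)
  nd <- length(s$depths)
  if (window %% 2 != 1 || window <= polyorder || window > nd)
    stop("window must be odd, greater than polyorder, and at most the number of planes")
  op <- sg_operator(nd, as.integer(window), as.integer(polyorder))
  dm <- dim(s$values)
  npix <- dm[1] * dm[2]
  M <- s$values
  dim(M) <- c(npix, nd)
  na <- is.na(M)
  M[na] <- 0
  out <- matrix(0, npix, nd)
  for (n in seq_len(nd)) {
    o <- op[[n]]
    acc <- numeric(npix)
    for (j in seq_along(o$idx)) {
      acc <- acc + o$w[j] * M[, o$idx[j]]
    }
    out[, n] <- acc
  }
  out[out < 0] <- 0
  out[na] <- NA_real_
  dim(out) <- dm
  structure(list(values = out, depths = s$depths, grid = s$grid),
            class = "sharpness_stack")
}

#' Collapse a DDB stack into a focus-stacked image and focal-depth map
#'
#' Per pixel, the focal plane is the depth of maximal (Savitzky-Golay
#' smoothed) sharpness; ties break toward the shallowest plane. The
#' focus-stacked pixel value is taken from the raw (unblurred) stack at the
#' focal plane, so focus stacking does not degrade WET accuracy. Planes where
#' the raw pixel is invalid are excluded from the argmax; a pixel invalid in
#' every plane is marked invalid.
#'
#' @param stack a `ddb_stack`
#' @param sigma Gaussian pre-blur sigma in pixels
#' @param sg_window,sg_polyorder Savitzky-Golay depth smoothing parameters;
#'   `sg_window = 1` disables smoothing
#' @return a `focus_result`: list with `fs_image` (mm WET), `focal_depth_map`
#'   (mm), `max_sharpness_map`, `valid` mask, `depths`, `grid`
#' @export
focus_stack <- function(stack, sigma = 1, sg_window = 11, sg_polyorder = 3) {
  stopifnot(inherits(stack, "ddb_stack"), length(stack$depths) >= 1)
  nd <- length(stack$depths)
  if (sg_window > 1 && sg_window > nd)
    sg_window <- if (nd %% 2 == 1) nd else nd - 1L
  s <- sharpness(stack, sigma)
  if (sg_window > 1 && sg_window > sg_polyorder)
    s <- smooth_depth_profiles(s, sg_window, sg_polyorder)
  dm <- dim(stack$images)
  npix <- dm[1] * dm[2]
  raw <- stack$images; dim(raw) <- c(npix, nd)
  score <- s$values;   dim(score) <- c(npix, nd)
  score[is.na(score)] <- -Inf
  score[is.na(raw)] <- -Inf
  best <- score[, 1]
  bestn <- rep(1L, npix)
  if (nd > 1) {
    for (n in 2:nd) {
      upd <- score[, n] > best
      best[upd] <- score[upd, n]
      bestn[upd] <- n
    }
  }
  # a pixel whose every candidate plane scored -Inf: fall back to the
  # shallowest raw-valid plane; invalid everywhere -> invalid pixel
  noscore <- !is.finite(best)
  if (any(noscore)) {
    anyvalid <- rowSums(!is.na(raw)) > 0
    fb <- which(noscore & anyvalid)
    if (length(fb))
      bestn[fb] <- apply(!is.na(raw[fb, , drop = FALSE]), 1, which.max)
  }
  valid <- rowSums(!is.na(raw)) > 0
  fs <- raw[cbind(seq_len(npix), bestn)]
  fs[!valid] <- NA_real_
  depth <- stack$depths[bestn]
  depth[!valid] <- NA_real_
  maxs <- best
  maxs[!is.finite(maxs)] <- NA_real_
  structure(list(
    fs_image = matrix(fs, dm[1], dm[2]),
    focal_depth_map = matrix(depth, dm[1], dm[2]),
    max_sharpness_map = matrix(maxs, dm[1], dm[2]),
    valid = matrix(valid, dm[1], dm[2]),
    depths = stack$depths, grid = stack$grid,
    sharpness = s
  ), class = "focus_result")
}

#' @export
print.focus_result <- function(x, ...) {
  cat(sprintf("focus_result: %d x %d pixels, %d planes over [%g, %g] mm, %d valid pixels\n",
              nrow(x$fs_image), ncol(x$fs_image), length(x$depths),
              min(x$depths), max(x$depths), sum(x$valid)))
  invisible(x)
}
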