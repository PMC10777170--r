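# Independent brute-force oracles and shared fixtures.

# reflect-padded index (edge-inclusive mirror), 1-based
reflect_ix <- function(i, n) {
  ifelse(i < 1, 1 - i, ifelse(i > n, 2 * n + 1 - i, i))
}

# dense per-pixel 2D convolution with reflect padding; taps accumulated in
# (ki outer, kj inner) order
brute_conv2 <- function(img, kernel) {
  nt <- nrow(img); nv <- ncol(img)
  kh <- nrow(kernel); kw <- ncol(kernel)
  ht <- (kh - 1) %/% 2; hv <- (kw - 1) %/% 2
  out <- matrix(0, nt, nv)
  for (i in seq_len(nt)) {
    for (j in seq_len(nv)) {
      acc <- 0
      for (ki in seq_len(kh)) {
        for (kj in seq_len(kw)) {
          ii <- reflect_ix(i + ki - 1 - ht, nt)
          jj <- reflect_ix(j + kj - 1 - hv, nv)
          acc <- acc + kernel[ki, kj] * img[ii, jj]
        }
      }
      out[i, j] <- acc
    }
  }
  out
}

# masked Gaussian blur, per pixel
brute_blur <- function(img, sigma = 1) {
  k <- pradstack::gaussian_kernel(sigma)
  mask <- !is.na(img)
  img0 <- img; img0[!mask] <- 0
  num <- brute_conv2(img0, k)
  den <- brute_conv2(mask * 1.0, k)
  out <- num / den
  out[den == 0] <- NA_real_
  out
}

# Savitzky-Golay weights by explicit polynomial least squares: value at
# position `at` (1-based within the window) of the degree-p fit
sg_weights_ls <- function(window, p, at) {
  x <- seq_len(window) - (window + 1) / 2
  V <- outer(x, 0:p, `^`)
  H <- V %*% solve(crossprod(V)) %*% t(V)
  H[at, ]
}

# brute-force per-pixel focus stacking: per-pixel argmax of the smoothed
# |Laplacian(blur)| profile, value looked up in the raw stack
brute_focus_stack <- function(stack, sigma = 1, sg_window = 11, sg_polyorder = 3) {
  nd <- length(stack$depths)
  dm <- dim(stack$images)
  sharp <- array(NA_real_, dm)
  lk <- pradstack::laplacian_kernel()
  for (n in seq_len(nd))
    sharp[, , n] <- abs(brute_conv2(brute_blur(stack$images[, , n], sigma), lk))
  # depth smoothing, per pixel, shared coefficient matrix
  if (sg_window > 1 && sg_window > sg_polyorder && sg_window <= nd) {
    FF <- signal::sgolay(p = sg_polyorder, n = sg_window)
    h <- (sg_window - 1) %/% 2
    sm <- array(NA_real_, dm)
    for (i in seq_len(dm[1])) {
      for (j in seq_len(dm[2])) {
        prof <- sharp[i, j, ]
        na <- is.na(prof)
        prof[na] <- 0
        out <- numeric(nd)
        for (n in seq_len(nd)) {
          if (n <= h) { idx <- 1:sg_window; w <- FF[n, ] }
          else if (n > nd - h) { idx <- (nd - sg_window + 1):nd; w <- FF[sg_window - (nd - n), ] }
          else { idx <- (n - h):(n + h); w <- FF[h + 1, ] }
          acc <- 0
          for (q in seq_along(idx)) acc <- acc + w[q] * prof[idx[q]]
          out[n] <- acc
        }
        out[out < 0] <- 0
        out[na] <- NA_real_
        sm[i, j, ] <- out
      }
    }
    sharp <- sm
  }
  fs <- matrix(NA_real_, dm[1], dm[2])
  dep <- matrix(NA_real_, dm[1], dm[2])
  for (i in seq_len(dm[1])) {
    for (j in seq_len(dm[2])) {
      raw <- stack$images[i, j, ]
      score <- sharp[i, j, ]
      score[is.na(score)] <- -Inf
      score[is.na(raw)] <- -Inf
      if (all(is.na(raw))) next
      n <- if (all(!is.finite(score))) which.max(!is.na(raw)) else which.max(score)
      fs[i, j] <- raw[n]
      dep[i, j] <- stack$depths[n]
    }
  }
  list(fs_image = fs, focal_depth_map = dep)
}

# hand-built ddb_stack from an image array (for focus/depth tests)
make_stack <- function(images, depths, pixel = 0.5) {
  grid <- pradstack::image_grid(pixel, c(dim(images)[1], dim(images)[2]) * pixel)
  structure(list(depths = depths, images = images,
                 counts = array(1L, dim(images)), grid = grid,
                 u_front = depths[1], u_rear = depths[length(depths)],
                 n_binned = rep(0L, length(depths)),
                 n_outside = rep(0L, length(depths)),
                 n_cut = rep(0L, length(depths))),
            class = "ddb_stack")
}

# stack whose planes hold an edge blurred by a per-plane Gaussian sigma
# (in pixels); edge at column `edge_col` boundary, amplitude `amp`
edge_stack <- function(nt = 32, nv = 32, sigmas, depths = NULL,
                       edge_col = NULL, base = 200, amp = 2.7, pixel = 0.5) {
  if (is.null(depths)) depths <- seq_along(sigmas) * 10
  if (is.null(edge_col)) edge_col <- nt / 2
  imgs <- array(NA_real_, c(nt, nv, length(sigmas)))
  x <- seq_len(nt) - (edge_col + 0.5)
  for (n in seq_along(sigmas)) {
    prof <- base + amp * stats::pnorm(x / sigmas[n])
    imgs[, , n] <- matrix(prof, nt, nv)
  }
  make_stack(imgs, depths, pixel)
}

# hand-made particle records data.frame with tracker attributes
make_records <- function(df, u_front = 0, u_rear = 200) {
  need <- c("t0", "v0", "st0", "sv0", "t1", "v1", "st1", "sv1",
            "e_in", "e_out", "wepl")
  for (nm in need) if (is.null(df[[nm]])) df[[nm]] <- 0
  df <- df[need]
  attr(df, "u_front") <- u_front
  attr(df, "u_rear") <- u_rear
  df
}

# memoized small full-physics cube-phantom run shared across test files
.fixtures <- new.env(parent = emptyenv())
small_run <- function() {
  if (is.null(.fixtures$small)) {
    ph <- pradstack::cube_phantom()
    rec <- pradstack::transport(
      ph, pradstack::beam_config(n_primaries = 3e5, rng_seed = 42),
      pradstack::transport_config())
    .fixtures$small <- list(phantom = ph, records = rec)
  }
  .fixtures$small
}
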