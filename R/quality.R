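# Image quality analysis: slanted-edge spatial resolution (oversampled ESF,
# error-function fit, MTF 10% fall-off frequency) and ROI noise.

#' Oversampled edge spread function from a slanted edge
#'
#' Projects pixel centres in a rectangular region straddling a (slightly
#' tilted) edge onto the edge-normal axis and pools the pixel values into
#' fixed-width distance bins. The tilt of the edge relative to the pixel grid
#' provides sub-pixel sampling of the edge profile.
#'
#' @param image nt x nv WET matrix (`NA` = invalid)
#' @param grid the [image_grid()] the image lives on
#' @param p0 a point on the edge (t, v), mm
#' @param normal edge normal (t, v), pointing in the direction of increasing
#'   WET; need not be normalized
#' @param half_len half-extent of the region along the edge, mm
#' @param half_width half-extent along the normal, mm
#' @param bin distance bin width, mm
#' @return data.frame with `distance` (bin centre, mm; negative = outside),
#'   `wet` (mean pixel value) and `n` (pixels pooled)
#' @export
slanted_edge_esf <- function(image, grid, p0, normal, half_len = 4,
                             half_width = 3.5, bin = 0.1) {
  stopifnot(length(p0) == 2, length(normal) == 2, bin > 0)
  nh <- normal / sqrt(sum(normal^2))
  eh <- c(-nh[2], nh[1])
  tt <- grid$t_centers; vv <- grid$v_centers
  dt <- rep(tt, times = grid$nv) - p0[1]
  dv <- rep(vv, each = grid$nt) - p0[2]
  d <- dt * nh[1] + dv * nh[2]
  a <- dt * eh[1] + dv * eh[2]
  val <- as.vector(image)
  sel <- abs(a) <= half_len & abs(d) <= half_width & !is.na(val)
  if (!any(sel)) stop("edge region contains no valid pixel")
  d <- d[sel]; val <- val[sel]
  ib <- floor((d + half_width) / bin)
  agg <- tapply(val, ib, mean)
  cnt <- tapply(val, ib, length)
  centers <- (as.numeric(names(agg)) + 0.5) * bin - half_width
  esf <- data.frame(distance = centers, wet = as.numeric(agg),
                    n = as.integer(cnt))
  esf <- esf[order(esf$distance), ]
  rownames(esf) <- NULL
  if (diff(range(esf$wet)) < 1e-9)
    warning("no detectable edge transition in the region; proceeding")
  esf
}

mtf10_coef <- sqrt(log(10) / (2 * pi^2))

#' MTF 10% fall-off frequency of a Gaussian line spread function
#'
#' Closed form: \eqn{\mathrm{MTF}_{10\%} = \sqrt{\ln 10/(2\pi^2)}/\sigma}.
#'
#' @param sigma edge (LSF) standard deviation, mm
#' @return frequency in lp/mm
#' @export
mtf10_from_sigma <- function(sigma) {
  stopifnot(all(sigma > 0))
  mtf10_coef / sigma
}

#' Fit an error function to an ESF and derive the MTF
#'
#' Weighted least-squares fit of
#' \eqn{\mathrm{ESF}(d) = b + A\,\Phi((d - c)/\sigma)} (\eqn{\Phi} the
#' standard normal CDF, equivalent to an error function). The line spread
#' function is then a Gaussian of width \eqn{\sigma}, whose Fourier transform
#' gives \eqn{\mathrm{MTF}(f) = \exp(-2\pi^2\sigma^2 f^2)} and
#' \eqn{\mathrm{MTF}_{10\%} = \sqrt{\ln 10/(2\pi^2)}/\sigma}. A discrete-FFT
#' evaluation of the same fitted LSF is available as a cross-check.
#'
#' @param esf data.frame from [slanted_edge_esf()] (columns `distance`,
#'   `wet`, optionally `n` used as weights)
#' @param pixel_size image pixel size, mm (sets the Nyquist frequency)
#' @param cap_nyquist cap the reported MTF10% at the pixel Nyquist frequency
#'   `1/(2 pixel_size)`; off by default since the fitted closed form can
#'   legitimately resolve beyond it
#' @param method `"analytic"` (closed form) or `"fft"` (discrete Fourier
#'   transform of the sampled fitted LSF)
#' @return an `mtf_curve`: list with `esf`, fitted `pars` (amplitude, center,
#'   sigma, offset), `mtf` samples (lp/mm vs modulation), `mtf10` (lp/mm),
#'   `capped`, `method`
#' @export
fit_esf_mtf <- function(esf, pixel_size = 0.5, cap_nyquist = FALSE,
                        method = c("analytic", "fft")) {
  method <- match.arg(method)
  stopifnot(is.data.frame(esf), nrow(esf) >= 10)
  d <- esf$distance; y <- esf$wet
  w <- if (!is.null(esf$n)) esf$n else rep(1, length(d))
  ord <- order(d); d <- d[ord]; y <- y[ord]; w <- w[ord]
  ntail <- max(3L, round(0.2 * length(d)))
  lo <- mean(head(y, ntail)); hi <- mean(tail(y, ntail))
  amp0 <- hi - lo
  c0 <- d[which.min(abs(y - (lo + hi) / 2))]
  # moment-based width of the numerical LSF as the starting sigma
  lsf0 <- pmax(diff(y) / diff(d), 0)
  dm <- (d[-1] + d[-length(d)]) / 2
  sg0 <- if (sum(lsf0) > 0)
    sqrt(sum(lsf0 * (dm - c0)^2) / sum(lsf0)) else median(diff(d))
  sg0 <- min(max(sg0, median(diff(d))), diff(range(d)) / 2)
  fit <- NULL
  for (sg_try in unique(c(sg0, 2 * sg0, 0.5 * sg0, 0.3, 0.6, 1.2))) {
    fit <- tryCatch(minpack.lm::nlsLM(
      y ~ b + A * pnorm((d - ctr) / sg),
      start = list(b = lo, A = amp0, ctr = c0, sg = sg_try), weights = w,
      lower = c(b = -Inf, A = 0, ctr = min(d), sg = 1e-4),
      upper = c(b = Inf, A = Inf, ctr = max(d), sg = diff(range(d))),
      control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (!is.null(fit)) break
  }
  if (is.null(fit))
    stop("edge fit failed to converge from any starting width; ",
         "check that the region straddles a single edge")
  pars <- coef(fit)
  sg <- unname(pars["sg"])
  if (sg <= 0 || !is.finite(sg)) stop("edge fit failed: non-positive sigma")
  freq <- seq(0, 3, by = 0.01)
  if (method == "analytic") {
    mtf <- exp(-2 * pi^2 * sg^2 * freq^2)
    mtf10 <- mtf10_coef / sg
  } else {
    dx <- 0.005
    nfft <- 8192
    x <- (seq_len(nfft) - nfft / 2) * dx
    lsf <- exp(-x^2 / (2 * sg^2))
    sp <- abs(fft(lsf))
    sp <- sp / sp[1]
    fgrid <- (seq_len(nfft) - 1) / (nfft * dx)
    half <- seq_len(nfft %/% 2)
    mtf <- approx(fgrid[half], sp[half], xout = freq, rule = 2)$y
    i <- which(sp[half] < 0.1)[1]
    mtf10 <- approx(sp[c(i - 1, i)], fgrid[c(i - 1, i)], xout = 0.1)$y
  }
  capped <- FALSE
  nyq <- 1 / (2 * pixel_size)
  if (cap_nyquist && mtf10 > nyq) {
    mtf10 <- nyq
    capped <- TRUE
  }
  structure(list(
    esf = data.frame(distance = d, wet = y, n = w),
    pars = c(amplitude = unname(pars["A"]), center = unname(pars["ctr"]),
             sigma = sg, offset = unname(pars["b"])),
    mtf = data.frame(freq = freq, mtf = mtf),
    mtf10 = unname(mtf10), capped = capped, method = method
  ), class = "mtf_curve")
}

#' @export
print.mtf_curve <- function(x, ...) {
  cat(sprintf("mtf_curve: edge sigma %.3f mm, MTF10%% = %.3f lp/mm%s (%s)\n",
              x$pars["sigma"], x$mtf10, if (x$capped) " [capped]" else "",
              x$method))
  invisible(x)
}

#' Edge descriptors of a cube insert
#'
#' Midpoints and inward normals of the four lateral edges of a (tilted) cube,
#' for slanted-edge analysis.
#'
#' @param phantom a [cube_phantom()]
#' @param cube cube index (1-based, ordered by depth)
#' @return list of four edges, each `list(p0, normal)`
#' @export
cube_edges <- function(phantom, cube) {
  stopifnot(inherits(phantom, "cube_phantom"),
            cube >= 1, cube <= nrow(phantom$cubes))
  cb <- phantom$cubes[cube, ]
  th <- phantom$tilt_deg * pi / 180
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  half <- phantom$cube_edge / 2
  ctr <- c(cb$tc, cb$vc)
  lapply(list(c(-half, 0), c(half, 0), c(0, -half), c(0, half)), function(off) {
    list(p0 = ctr + as.vector(R %*% off),
         normal = as.vector(R %*% (-off / half)))
  })
}

#' Four-edge averaged MTF of a cube insert
#'
#' Extracts the oversampled ESF at each of the cube's four lateral edges
#' (distance measured along the inward normal, so all profiles rise),
#' averages them bin-by-bin, and fits the combined ESF.
#'
#' @param image WET image matrix
#' @param grid the [image_grid()]
#' @param phantom a [cube_phantom()]
#' @param cube cube index
#' @param half_len,half_width,bin region parameters, see [slanted_edge_esf()]
#' @param ... passed to [fit_esf_mtf()]
#' @return an `mtf_curve`
#' @export
cube_mtf <- function(image, grid, phantom, cube, half_len = 4,
                     half_width = 3.5, bin = 0.1, ...) {
  edges <- cube_edges(phantom, cube)
  esfs <- lapply(edges, function(e)
    slanted_edge_esf(image, grid, e$p0, e$normal, half_len, half_width, bin))
  all <- do.call(rbind, esfs)
  agg <- stats::aggregate(
    cbind(wsum = all$wet * all$n, n = all$n) ~ distance, data = all, FUN = sum)
  esf <- data.frame(distance = agg$distance, wet = agg$wsum / agg$n,
                    n = as.integer(agg$n))
  fit_esf_mtf(esf, ...)
}

#' Pixel statistics in a rectangular ROI
#'
#' @param image image matrix
#' @param grid the [image_grid()]
#' @param roi region `c(t0, t1, v0, v1)` in mm
#' @return list with `mean`, `sd`, `n` over the valid pixels
#' @export
roi_stats <- function(image, grid, roi) {
  stopifnot(length(roi) == 4, roi[2] > roi[1], roi[4] > roi[3])
  it <- which(grid$t_centers >= roi[1] & grid$t_centers <= roi[2])
  iv <- which(grid$v_centers >= roi[3] & grid$v_centers <= roi[4])
  px <- image[it, iv]
  px <- px[!is.na(px)]
  if (length(px) < 2) stop("ROI contains fewer than 2 valid pixels")
  list(mean = mean(px), sd = sd(px), n = length(px))
}

#' Inter-pixel noise in a homogeneous ROI
#'
#' Standard deviation of the valid pixel values in a rectangular region.
#'
#' @inheritParams roi_stats
#' @return noise in mm WET
#' @export
roi_noise <- function(image, grid, roi) {
  roi_stats(image, grid, roi)$sd
}
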