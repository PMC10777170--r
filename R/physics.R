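#' @useDynLib pradstack, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats median quantile sd coef fft approx setNames pnorm dnorm
#' @importFrom utils modifyList head tail
#' @importFrom data.table fread fwrite setDT setattr
NULL

# Physics constants (protons in water)
.const <- list(
  alpha   = 0.022,   # Bragg-Kleeman coefficient, mm * MeV^-p
  p       = 1.77,    # Bragg-Kleeman exponent
  X0      = 360.8,   # radiation length of water, mm
  m_p     = 938.272, # proton rest mass, MeV
  bohr    = 0.0087,  # Bohr straggling variance rate in water, MeV^2/mm
  e_cut   = 1.0      # transport energy cutoff, MeV
)

#' Residual range of a proton in water
#'
#' Bragg-Kleeman closed form \eqn{R(E) = \alpha E^p} with
#' \eqn{\alpha = 0.022} mm MeV\eqn{^{-p}} and \eqn{p = 1.77}.
#'
#' @param e kinetic energy in MeV (vectorized, all > 0)
#' @return residual range in mm of water
#' @export
#' @examples
#' residual_range(200) # ~259.6 mm
residual_range <- function(e) {
  stopifnot(is.numeric(e), all(is.finite(e)), all(e > 0))
  .const$alpha * e^.const$p
}

#' Energy with a given residual range in water
#'
#' Inverse of [residual_range()].
#'
#' @param r residual range in mm of water (> 0)
#' @return kinetic energy in MeV
#' @export
energy_from_range <- function(r) {
  stopifnot(is.numeric(r), all(is.finite(r)), all(r > 0))
  (r / .const$alpha)^(1 / .const$p)
}

#' Water stopping power of a proton
#'
#' Derived from the Bragg-Kleeman relation: \eqn{S(E) = (dR/dE)^{-1} =
#' E^{1-p} / (\alpha p)}.
#'
#' @param e kinetic energy in MeV (> 0)
#' @return stopping power in MeV/mm of water
#' @export
stopping_power <- function(e) {
  stopifnot(is.numeric(e), all(is.finite(e)), all(e > 0))
  e^(1 - .const$p) / (.const$alpha * .const$p)
}

#' Water-equivalent path length from an energy-loss pair
#'
#' Integrates the inverse water stopping power from the residual to the
#' initial energy, which for the Bragg-Kleeman closed form reduces to
#' \eqn{R(E_{in}) - R(E_{out})}.
#'
#' @param e_in initial kinetic energy, MeV
#' @param e_out residual kinetic energy, MeV; must satisfy
#'   `0 < e_out <= e_in` elementwise
#' @return water-equivalent path length in mm
#' @export
#' @examples
#' compute_wepl(200, 200)  # 0
compute_wepl <- function(e_in, e_out) {
  stopifnot(is.numeric(e_in), is.numeric(e_out),
            all(is.finite(e_in)), all(is.finite(e_out)),
            all(e_out > 0))
  if (any(e_out > e_in))
    stop("invalid record: e_out > e_in")
  residual_range(e_in) - residual_range(e_out)
}

# beta*c*p in MeV for a proton of kinetic energy e
beta_c_p <- function(e) {
  m <- .const$m_p
  (e^2 + 2 * e * m) / (e + m)
}

#' Highland multiple-Coulomb-scattering angle
#'
#' Standard deviation of the projected scattering angle for a proton of
#' kinetic energy `e` after traversing `path_mm` of water:
#' \deqn{\theta_0 = \frac{13.6\,\mathrm{MeV}}{\beta c p}
#'   \sqrt{x/X_0}\,\left(1 + 0.038 \ln(x/X_0)\right)}
#' with \eqn{X_0 = 360.8} mm. The logarithmic correction is floored at zero
#' so that \eqn{\theta_0 \to 0} as the path vanishes.
#'
#' @param e kinetic energy, MeV (> 0)
#' @param path_mm water-equivalent path, mm (> 0)
#' @return projected scattering angle sigma in rad
#' @export
#' @examples
#' highland_sigma(200, 200) # ~27 mrad
highland_sigma <- function(e, path_mm) {
  stopifnot(all(e > 0), all(path_mm > 0))
  xr <- path_mm / .const$X0
  corr <- pmax(1 + 0.038 * log(xr), 0)
  13.6 / beta_c_p(e) * sqrt(xr) * corr
}
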