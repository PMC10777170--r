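# Cubic-Hermite spline trajectory estimates between the two trackers.
# Depth is parameterized geometrically: s = (u - u_front) / (u_rear - u_front).

#' Fit cubic spline trajectory estimates to particle records
#'
#' Per transverse axis, a cubic Hermite interpolant on the normalized depth
#' with endpoint values equal to the measured tracker positions and endpoint
#' tangents equal to the measured slopes scaled by the depth span and the
#' tangent scale factors \eqn{\Lambda_0, \Lambda_1} (optimized-cubic-spline
#' family; the plain Hermite choice \eqn{\Lambda = 1} is the default).
#'
#' @param records particle records: a data.frame with columns `t0, v0, st0,
#'   sv0, t1, v1, st1, sv1` and attributes `u_front`/`u_rear` (as produced by
#'   [transport()] or [read_phase_space()]); tracker depths can be overridden
#'   with `u_front`/`u_rear`
#' @param lambda0,lambda1 tangent scale factors at the front and rear tracker
#' @param u_front,u_rear tracker depths, mm
#' @return a `path_estimate` object, evaluable with [lateral_at_depth()]
#' @export
fit_spline <- function(records, lambda0 = 1, lambda1 = 1,
                       u_front = attr(records, "u_front"),
                       u_rear = attr(records, "u_rear")) {
  stopifnot(!is.null(u_front), !is.null(u_rear), u_rear > u_front,
            is.finite(lambda0), is.finite(lambda1))
  need <- c("t0", "v0", "st0", "sv0", "t1", "v1", "st1", "sv1")
  if (!all(need %in% names(records)))
    stop("records lack required columns: ",
         paste(setdiff(need, names(records)), collapse = ", "))
  ok <- Reduce(`&`, lapply(need, function(nm) is.finite(records[[nm]])))
  if (!all(ok)) stop("invalid record: non-finite tracker measurements")
  D <- u_rear - u_front
  structure(list(
    t0 = records$t0, v0 = records$v0,
    dt0 = records$st0 * D * lambda0, dv0 = records$sv0 * D * lambda0,
    t1 = records$t1, v1 = records$v1,
    dt1 = records$st1 * D * lambda1, dv1 = records$sv1 * D * lambda1,
    u_front = u_front, u_rear = u_rear,
    lambda = c(lambda0, lambda1), n = length(records$t0)
  ), class = "path_estimate")
}

hermite_basis <- function(s) {
  s2 <- s * s; s3 <- s2 * s
  cbind(h00 = 2 * s3 - 3 * s2 + 1,
        h10 = s3 - 2 * s2 + s,
        h01 = -2 * s3 + 3 * s2,
        h11 = s3 - s2)
}

#' Lateral position of estimated trajectories at a depth
#'
#' Evaluates the fitted cubic splines; at the tracker depths the measured
#' positions are reproduced exactly.
#'
#' @param path a `path_estimate` from [fit_spline()]
#' @param u scalar depth in mm, within `[u_front, u_rear]`
#' @return a two-column matrix of lateral positions `(t, v)` in mm, one row
#'   per event
#' @export
lateral_at_depth <- function(path, u) {
  stopifnot(inherits(path, "path_estimate"), length(u) == 1)
  if (u < path$u_front || u > path$u_rear)
    stop("depth outside the tracker span [", path$u_front, ", ", path$u_rear, "]")
  s <- (u - path$u_front) / (path$u_rear - path$u_front)
  h <- hermite_basis(s)
  cbind(
    t = h[, 1] * path$t0 + h[, 2] * path$dt0 + h[, 3] * path$t1 + h[, 4] * path$dt1,
    v = h[, 1] * path$v0 + h[, 2] * path$dv0 + h[, 3] * path$v1 + h[, 4] * path$dv1)
}
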