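#' Axial orientation angle phi
#'
#' For a nonzero 3-vector `v = (x, y, z)` in RAS world axes, project into
#' the axial plane, `d' = (x, y)`, and measure the signed angle between
#' `d'` and the medial-lateral (x) axis, parameterized so that
#'
#' * `phi = 0` when `d'` aligns with the anterior-posterior axis (either
#'   half: the statistic is A/P symmetric),
#' * `phi` decreases to `-90` as `d'` rotates toward the *right* half of
#'   the M-L axis (`+x`), reaching `-90` exactly on it,
#' * `phi` increases to `+90` as `d'` rotates toward the *left* half
#'   (`-x`), reaching `+90` exactly on it.
#'
#' Defined values lie in `[-90, 90]` degrees and satisfy
#' `phi(-v) = -phi(v)`.  When the axial projection is (numerically) zero —
#' `||d'|| <= tol * ||v||` — the angle is undefined and `NA` is returned;
#' callers must exclude (and count) such directions rather than drop them
#' silently.
#'
#' @param v numeric 3-vector (any positive scale; the angle is
#'   scale-invariant).
#' @param tol relative tolerance for the undefined test (default `1e-8`).
#' @return angle in degrees in `[-90, 90]`, or `NA_real_` if undefined.
#' @export
orientation_angle <- function(v, tol = 1e-8) {
  v <- as.numeric(v)
  if (length(v) != 3L || !all(is.finite(v)))
    stop("orientation_angle: 'v' must be a finite 3-vector")
  nv <- sqrt(sum(v^2))
  if (nv == 0) stop("orientation_angle: zero vector has no orientation")
  na <- sqrt(v[1]^2 + v[2]^2)
  if (na <= tol * nv) return(NA_real_)
  if (v[1] == 0) return(0)
  acute <- atan2(abs(v[2]), abs(v[1])) * 180 / pi  # d' vs x-axis, in [0, 90]
  -sign(v[1]) * (90 - acute)
}

#' Orientation angles for every direction of a set
#'
#' Vectorized [orientation_angle()].  Undefined entries (axial projection
#' numerically zero) are flagged, never dropped: the returned object keeps
#' one slot per direction.
#'
#' @param ds a [direction_set()] (or a plain 3-column matrix of nonzero
#'   vectors).
#' @param tol relative tolerance for the undefined test.
#' @return An object of class `orientation_angles`: a list with `phi`
#'   (degrees, `NA` where undefined), `axial` (n x 2 matrix of axial
#'   projections), `defined` (logical), and `n_undefined`.
#' @export
orientation_angles <- function(ds, tol = 1e-8) {
  v <- unclass(as.matrix(ds))
  storage.mode(v) <- "double"
  nv <- sqrt(rowSums(v^2))
  if (any(nv == 0)) stop("orientation_angles: zero vector present")
  axial <- v[, 1:2, drop = FALSE]
  na <- sqrt(rowSums(axial^2))
  defined <- na > tol * nv
  acute <- atan2(abs(v[, 2]), abs(v[, 1])) * 180 / pi
  phi <- -sign(v[, 1]) * (90 - acute)
  phi[v[, 1] == 0] <- 0
  phi[!defined] <- NA_real_
  structure(list(phi = phi, axial = axial, defined = defined,
                 n_undefined = sum(!defined)),
            class = "orientation_angles")
}

#' @export
print.orientation_angles <- function(x, ...) {
  cat(sprintf("<orientation_angles> %d directions (%d undefined)\n",
              length(x$phi), x$n_undefined))
  if (any(x$defined))
    cat(sprintf("  phi range: [%.1f, %.1f] deg\n",
                min(x$phi, na.rm = TRUE), max(x$phi, na.rm = TRUE)))
  invisible(x)
}
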