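#' Antipodally symmetric direction sets
#'
#' A `direction_set` is a matrix of 3-component unit vectors (rows) that is
#' closed under negation: for every vector `v` the set also contains `-v`.
#' Orientation densities (fODFs) are defined on lines, not rays, so all
#' per-direction quantities in this package index into such a set.  World
#' axes are RAS: +x right (medial-lateral), +y anterior (anterior-posterior),
#' +z superior.
#'
#' @param vectors numeric matrix with 3 columns; rows must be unit vectors
#'   and the set must be antipodally closed (tolerance `1e-9`).
#' @return An object of class `direction_set`: the vector matrix with
#'   attributes `n` (number of directions).
#' @seealso [build_sphere()], [default_sphere()]
#' @export
direction_set <- function(vectors) {
  vectors <- as.matrix(vectors)
  if (ncol(vectors) != 3L)
    stop("direction_set: 'vectors' must have 3 columns")
  storage.mode(vectors) <- "double"
  nrm <- sqrt(rowSums(vectors^2))
  if (any(abs(nrm - 1) > 1e-9))
    stop("direction_set: all vectors must have unit norm (tolerance 1e-9)")
  if (nrow(vectors) %% 2L != 0L)
    stop("direction_set: count must be even (antipodal closure)")
  if (!.antipodally_closed(vectors, tol = 1e-9))
    stop("direction_set: set is not antipodally closed within 1e-9")
  dimnames(vectors) <- NULL
  structure(vectors, n = nrow(vectors), class = "direction_set")
}

.antipodally_closed <- function(v, tol = 1e-9) {
  # nearest neighbour of -v_i must be within tol
  g <- v %*% t(v)                      # gram matrix
  # for each i, does some j have v_j ~= -v_i?  equivalent to g[i, j] ~= -1
  all(apply(g, 1L, min) < -1 + 0.5 * tol^2 + 1e-15)
}

#' @export
print.direction_set <- function(x, ...) {
  cat(sprintf("<direction_set> %d antipodally paired unit vectors\n",
              attr(x, "n")))
  cat(sprintf("  minimum inter-line angle: %.2f deg\n", min_line_angle(x)))
  invisible(x)
}

#' Minimum angular separation between distinct lines of a direction set
#'
#' The angle between two lines is the acute angle between their direction
#' vectors, `acos(|v_i . v_j|)`; the minimum is taken over all distinct
#' antipodal pairs.
#'
#' @param ds a [direction_set()].
#' @return minimum inter-line angle in degrees.
#' @export
min_line_angle <- function(ds) {
  v <- unclass(ds)
  g <- abs(v %*% t(v))
  diag(g) <- 0
  # exclude each vector's own antipode (|dot| ~ 1 identifies both self & pair)
  g[g > 1 - 1e-12] <- 0
  acos(min(1, max(g))) * 180 / pi
}

#' Build an antipodally symmetric sphere by electrostatic repulsion
#'
#' Places `n_pairs` antipodal pairs of unit vectors so that the minimum
#' angular separation between lines is (approximately) maximized, by a
#' deterministic Coulomb-repulsion descent started from a seeded random
#' configuration.  The same `(n_pairs, optimization_seed)` always yields a
#' bit-identical set, so all subjects of a cohort can share one direction
#' index.
#'
#' @param n_pairs number of antipodal pairs (>= 6); the result has
#'   `2 * n_pairs` vectors.  The default 181 pairs gives the 362-direction
#'   set used throughout the package.
#' @param optimization_seed integer seed for the initial configuration.
#' @param n_iter number of descent iterations.
#' @return a [direction_set()] with `2 * n_pairs` vectors, ordered so that
#'   row `i + n_pairs` is the antipode of row `i`.
#' @export
build_sphere <- function(n_pairs = 181L, optimization_seed = 20260101L,
                         n_iter = 600L) {
  n_pairs <- as.integer(n_pairs)
  if (is.na(n_pairs) || n_pairs < 6L)
    stop("build_sphere: n_pairs must be >= 6")
  set.seed(as.integer(optimization_seed))
  # uniform init on the sphere
  p <- matrix(stats::rnorm(3L * n_pairs), ncol = 3L)
  p <- p / sqrt(rowSums(p^2))
  step <- 0.1 / n_pairs
  for (it in seq_len(n_iter)) {
    f <- .repulsion_force(p)
    p <- p + step * f
    p <- p / sqrt(rowSums(p^2))
  }
  direction_set(rbind(p, -p))
}

# Coulomb force between lines: each point repels every other point and every
# antipode; the net force is projected implicitly by renormalization.
.repulsion_force <- function(p) {
  n <- nrow(p)
  f <- matrix(0, n, 3L)
  for (s in c(1, -1)) {
    dx <- outer(p[, 1], s * p[, 1], "-")
    dy <- outer(p[, 2], s * p[, 2], "-")
    dz <- outer(p[, 3], s * p[, 3], "-")
    d2 <- dx^2 + dy^2 + dz^2
    d2[d2 < 1e-12] <- Inf
    w <- d2^(-1.5)
    f <- f + cbind(rowSums(dx * w), rowSums(dy * w), rowSums(dz * w))
  }
  # cap the force so a pathological near-coincidence cannot explode a step
  fn <- sqrt(rowSums(f^2))
  cap <- stats::median(fn) * 10
  too <- fn > cap
  if (any(too)) f[too, ] <- f[too, ] * (cap / fn[too])
  f
}

#' The package's default 362-direction set
#'
#' Loads the versioned 181-pair direction fixture shipped with the package
#' (result of `build_sphere(181)` with the packaged seed).  Using a frozen
#' fixture guarantees that every subject, cohort and session indexes fODF
#' densities identically.
#'
#' @return a [direction_set()] with 362 vectors.
#' @export
default_sphere <- function() {
  if (!is.null(.sphere_cache$ds)) return(.sphere_cache$ds)
  path <- system.file("extdata", "sphere362.tsv", package = "odfreweight")
  ds <- if (nzchar(path)) read_direction_tsv(path) else build_sphere()
  .sphere_cache$ds <- ds
  ds
}

.sphere_cache <- new.env(parent = emptyenv())

#' Read / write direction sets as TSV
#'
#' The on-disk form is a tab-separated table with columns `x`, `y`, `z`,
#' one row per direction, in the same order as the fourth axis of an fODF
#' volume.  The reader validates unit norm and antipodal closure.
#'
#' @param path file path.
#' @return `read_direction_tsv()` returns a [direction_set()];
#'   `write_direction_tsv()` returns `path` invisibly.
#' @export
read_direction_tsv <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           colClasses = "numeric")
  if (!all(c("x", "y", "z") %in% names(tab)))
    stop("direction TSV must have columns x, y, z")
  direction_set(as.matrix(tab[, c("x", "y", "z")]))
}

#' @rdname read_direction_tsv
#' @param ds a [direction_set()] to write.
#' @export
write_direction_tsv <- function(ds, path) {
  stopifnot(inherits(ds, "direction_set"))
  df <- data.frame(x = ds[, 1], y = ds[, 2], z = ds[, 3])
  # full double precision so the fixture round-trips bit-exactly
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("x\ty\tz", con)
  writeLines(sprintf("%.17g\t%.17g\t%.17g", df$x, df$y, df$z), con)
  invisible(path)
}
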