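# Shared fixtures, built in code.

# a small antipodal direction set: +-x, +-y, +-z plus diagonal pairs
small_dirs <- function() {
  v <- rbind(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1),
             c(1, 1, 0) / sqrt(2), c(1, 0, 1) / sqrt(2))
  direction_set(rbind(v, -v))
}

# axial 4-direction set: +-x (phi = -90/+90), +-y (phi = 0)
axial_dirs <- function() {
  direction_set(rbind(c(1, 0, 0), c(0, 1, 0), c(-1, 0, 0), c(0, -1, 0)))
}

# an fodf_field with given grid and per-voxel densities drawn uniformly
random_fodf <- function(grid, dirs, seed, lo = 0, hi = 1) {
  set.seed(seed)
  n <- attr(dirs, "n")
  fodf_field(array(runif(prod(grid) * n, lo, hi), dim = c(grid, n)),
             directions = dirs)
}

# small phantom parameter sets for unit tests
small_phantom <- function(...) {
  args <- utils::modifyList(list(grid_shape = c(10, 10, 8),
                                 n_subjects = 3, master_seed = 42),
                            list(...))
  do.call(phantom_params, args)
}

# exact traversal oracle: a voxel is crossed iff the segment intersects
# its cube (slab clipping per axis), with voxel centers at 0-based ijk
clip_traversal_oracle <- function(points, grid) {
  seen <- integer(0)
  for (s in seq_len(nrow(points) - 1L)) {
    a <- points[s, ]; b <- points[s + 1L, ]
    lo <- pmax(1L, floor(pmin(a, b) + 0.5) + 1L)
    hi <- pmin(grid, floor(pmax(a, b) + 0.5) + 1L)
    if (any(lo > hi)) next
    for (vz in lo[3]:hi[3]) for (vy in lo[2]:hi[2]) for (vx in lo[1]:hi[1]) {
      c0 <- c(vx, vy, vz) - 1L
      t0 <- 0; t1 <- 1; ok <- TRUE
      for (k in 1:3) {
        d <- b[k] - a[k]
        if (abs(d) < 1e-300) {
          if (a[k] < c0[k] - 0.5 || a[k] > c0[k] + 0.5) { ok <- FALSE; break }
        } else {
          tt <- sort(c((c0[k] - 0.5 - a[k]) / d, (c0[k] + 0.5 - a[k]) / d))
          t0 <- max(t0, tt[1]); t1 <- min(t1, tt[2])
          if (t0 > t1) { ok <- FALSE; break }
        }
      }
      if (ok)
        seen <- c(seen, vx + (vy - 1L) * grid[1] +
                    (vz - 1L) * grid[1] * grid[2])
    }
  }
  sort(unique(seen))
}

# one default-size corridor cohort, generated once per test run
default_corridor_cohort <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- generate_cohort(phantom_params(), region = "corridor")
    cache
  }
})

# round doubles through IEEE float32 (the on-disk NIfTI datatype)
.float32 <- function(x) {
  readBin(writeBin(as.numeric(x), raw(), size = 4L), "numeric",
          n = length(x), size = 4L)
}

.float32_mat <- function(m) matrix(.float32(t(m)), ncol = 3, byrow = TRUE)

# independent scalar oracle for the orientation angle, built from the
# geometric definition with acos (the implementation uses atan2)
phi_oracle <- function(v, tol = 1e-8) {
  nv <- sqrt(sum(v^2))
  d2 <- v[1:2]
  if (sqrt(sum(d2^2)) <= tol * nv) return(NA_real_)
  acute <- acos(min(1, abs(d2[1]) / sqrt(sum(d2^2)))) * 180 / pi
  mag <- 90 - acute
  if (v[1] > 0) -mag else if (v[1] < 0) mag else 0
}
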