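#' Streamline density volume
#'
#' Per voxel, the number of *valid* streamlines passing through it divided
#' by the total number of valid streamlines.  A streamline counts at most
#' once per voxel regardless of re-entry (set semantics); voxel traversal
#' uses a 3-D digital differential analyzer over each polyline segment, so
#' voxels crossed between consecutive points are counted even when the
#' step length exceeds the voxel edge.
#'
#' @param ss a `streamline_set` from [propagate()].
#' @param grid_shape integer 3-vector of the target grid.
#' @param affine voxel-to-world matrix of the target grid (default: the
#'   tracking affine).
#' @return An object of class `density_volume`: list with `density` (3-D
#'   array in `[0, 1]`), `n_valid_streamlines`, `affine`.
#' @export
streamline_density <- function(ss, grid_shape, affine = NULL) {
  stopifnot(inherits(ss, "streamline_set"))
  if (is.null(affine)) affine <- ss$affine
  grid_shape <- as.integer(grid_shape)
  valid <- which(ss$status == "valid_gm_termination")
  if (length(valid) == 0L)
    stop("streamline_density: no valid streamlines", call. = FALSE)
  inv <- solve(affine)
  counts <- array(0L, dim = grid_shape)
  for (q in valid) {
    vox <- .traversed_voxels(ss$polylines[[q]], inv, grid_shape)
    counts[vox] <- counts[vox] + 1L
  }
  structure(list(density = counts / length(valid),
                 n_valid_streamlines = length(valid),
                 affine = affine),
            class = "density_volume")
}

#' @export
print.density_volume <- function(x, ...) {
  cat(sprintf("<density_volume> grid %s, %d valid streamlines\n",
              paste(dim(x$density), collapse = "x"),
              x$n_valid_streamlines))
  cat(sprintf("  nonzero voxels: %d; max density %.3f\n",
              sum(x$density > 0), max(x$density)))
  invisible(x)
}

# unique linear voxel indices traversed by a polyline (Amanatides-Woo per
# segment, on 0-based voxel coordinates with voxel centers at integers)
.traversed_voxels <- function(points, inv, grid_shape) {
  n <- nrow(points)
  vc <- cbind(points, 1) %*% t(inv)          # continuous voxel coords
  q <- vc[, 1:3, drop = FALSE] + 0.5         # cell coords: cell = floor(q)
  seen <- integer(0)
  for (s in seq_len(n - 1L)) {
    a <- q[s, ]; b <- q[s + 1L, ]
    cell <- floor(a)
    endc <- floor(b)
    dirv <- b - a
    stepv <- sign(dirv)
    tmax <- rep(Inf, 3); tdel <- rep(Inf, 3)
    for (k in 1:3) {
      if (stepv[k] != 0) {
        bound <- cell[k] + (stepv[k] > 0)
        tmax[k] <- (bound - a[k]) / dirv[k]
        tdel[k] <- abs(1 / dirv[k])
      }
    }
    seen <- c(seen, .cell_index(cell, grid_shape))
    guard <- sum(abs(endc - cell)) + 3L
    while (any(cell != endc) && guard > 0L) {
      k <- which.min(tmax)
      if (!is.finite(tmax[k]) || tmax[k] > 1) break
      cell[k] <- cell[k] + stepv[k]
      tmax[k] <- tmax[k] + tdel[k]
      seen <- c(seen, .cell_index(cell, grid_shape))
      guard <- guard - 1L
    }
  }
  if (n == 1L) seen <- .cell_index(floor(q[1, ]), grid_shape)
  unique(seen[!is.na(seen)])
}

.cell_index <- function(cell, grid_shape) {
  v <- cell + 1L                              # 1-based voxel index
  if (any(v < 1) || any(v > grid_shape)) return(NA_integer_)
  as.integer(v[1] + (v[2] - 1L) * grid_shape[1] +
               (v[3] - 1L) * grid_shape[1] * grid_shape[2])
}

#' Streamline-density shares over target ROIs
#'
#' Per target mask, the mean density over its voxels; shares are the
#' means normalized over all targets so that, for a fixed seed, they sum
#' to 1.
#'
#' @param d a [streamline_density()] volume.
#' @param targets named list of disjoint logical masks on the density
#'   grid.
#' @return data frame with columns `target_label`, `raw_mean_density`,
#'   `normalized_share` (all `NA` shares, flagged via attribute
#'   `all_zero = TRUE`, if every mean is zero), and attribute
#'   `normalization_mode = "over_targets"`.
#' @export
roi_share <- function(d, targets) {
  stopifnot(inherits(d, "density_volume"), is.list(targets),
            length(targets) >= 1L)
  if (is.null(names(targets)))
    names(targets) <- sprintf("target-%d", seq_along(targets))
  overlap <- Reduce(`+`, lapply(targets, function(m) m * 1L))
  if (max(overlap) > 1L)
    stop("roi_share: target masks overlap", call. = FALSE)
  means <- vapply(targets, function(m) {
    if (sum(m) == 0L) stop("roi_share: empty target mask", call. = FALSE)
    mean(d$density[m])
  }, numeric(1))
  tot <- sum(means)
  shares <- if (tot > 0) means / tot else rep(NA_real_, length(means))
  out <- data.frame(target_label = names(targets),
                    raw_mean_density = unname(means),
                    normalized_share = unname(shares))
  attr(out, "normalization_mode") <- "over_targets"
  attr(out, "all_zero") <- tot <= 0
  out
}

#' White-matter-normalized ROI density
#'
#' The cross-voxel mean density in an ROI divided by the cross-voxel mean
#' density in the whole WM mask.  Any log transform for statistical
#' comparison is left to the caller.
#'
#' @param d a [streamline_density()] volume.
#' @param roi,wm nonempty logical masks on the density grid.
#' @return scalar ratio.
#' @export
wm_normalized_density <- function(d, roi, wm) {
  stopifnot(inherits(d, "density_volume"))
  if (sum(roi) == 0L) stop("wm_normalized_density: empty ROI mask")
  if (sum(wm) == 0L) stop("wm_normalized_density: empty WM mask")
  wm_mean <- mean(d$density[wm])
  if (wm_mean <= 0)
    stop("wm_normalized_density: zero mean density in WM", call. = FALSE)
  mean(d$density[roi]) / wm_mean
}

#' Mean principal-diffusivity direction fractions over an ROI
#'
#' For a volume of per-voxel 3-channel direction weights (RGB-coded
#' medial-lateral, anterior-posterior, superior-inferior), normalizes
#' each voxel's channels to fractions and averages them over the ROI.
#' Voxels whose channels are all zero are excluded with a logged count.
#'
#' @param v1_rgb 4-D array `(i, j, k, channel)` with 3 nonnegative
#'   channels.
#' @param roi logical 3-D mask.
#' @return named numeric vector `c(ml, ap, si)` summing to 1, with
#'   attribute `n_excluded`.
#' @export
direction_fractions <- function(v1_rgb, roi) {
  d <- dim(v1_rgb)
  stopifnot(length(d) == 4L, d[4] == 3L, identical(dim(roi), d[1:3]))
  if (any(v1_rgb < 0)) stop("direction_fractions: negative channel values")
  cells <- .mask_cells(roi, 3L)
  m <- matrix(v1_rgb[cells], ncol = 3L)
  tot <- rowSums(m)
  keep <- tot > 0
  if (!any(keep))
    stop("direction_fractions: all ROI voxels have zero channels")
  fr <- colMeans(m[keep, , drop = FALSE] / tot[keep])
  structure(stats::setNames(fr, c("ml", "ap", "si")),
            n_excluded = sum(!keep))
}

#' Bundle overlap fractions within an ROI
#'
#' For each (possibly overlapping) bundle mask, the number of its voxels
#' inside the ROI divided by the total overlapping voxel count across all
#' bundles; the fractions sum to 1 by construction.
#'
#' @param bundle_masks named list of logical masks.
#' @param roi nonempty logical mask on the same grid.
#' @return named numeric vector of fractions.
#' @export
bundle_overlap_fractions <- function(bundle_masks, roi) {
  stopifnot(is.list(bundle_masks), length(bundle_masks) >= 1L,
            sum(roi) > 0L)
  if (is.null(names(bundle_masks)))
    names(bundle_masks) <- sprintf("bundle-%d", seq_along(bundle_masks))
  counts <- vapply(bundle_masks, function(m) sum(m & roi), numeric(1))
  tot <- sum(counts)
  if (tot == 0)
    stop("bundle_overlap_fractions: no bundle overlaps the ROI",
         call. = FALSE)
  counts / tot
}
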