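#' Subject-aligned fODF cohorts
#'
#' A `cohort_fodf` stacks the fODF fields of two or more subjects sampled
#' on an identical grid, affine and [direction_set()], together with a
#' binary region-of-interest mask marking the voxels to be processed by
#' [cross_subject_std()] and [reweight_cohort()].
#'
#' @param fields list of [fodf_field()] objects (one per subject), all
#'   sharing grid shape, affine and direction set.
#' @param roi_mask logical 3-D array on the same grid (default: all voxels).
#' @param subject_ids character labels (default `"sub-01"`, ...).
#' @return An object of class `cohort_fodf`: list with `stack` (5-D array
#'   `(subject, i, j, k, direction)`), `roi_mask`, `affine`, `directions`,
#'   `subject_ids`.
#' @export
cohort_fodf <- function(fields, roi_mask = NULL, subject_ids = NULL) {
  if (!is.list(fields) || length(fields) < 2L)
    stop("cohort_fodf: need at least 2 subjects", call. = FALSE)
  if (!all(vapply(fields, inherits, logical(1), "fodf_field")))
    stop("cohort_fodf: 'fields' must be a list of fodf_field objects")
  d0 <- dim(fields[[1]]$densities)
  a0 <- fields[[1]]$affine
  v0 <- unclass(fields[[1]]$directions)
  for (f in fields[-1]) {
    if (!identical(dim(f$densities), d0))
      stop("cohort_fodf: grid shapes differ across subjects")
    if (max(abs(f$affine - a0)) > 1e-9)
      stop("cohort_fodf: affines differ across subjects")
    if (max(abs(unclass(f$directions) - v0)) > 1e-9)
      stop("cohort_fodf: direction sets differ across subjects")
  }
  ns <- length(fields)
  stack <- array(0, dim = c(ns, d0))
  m <- matrix(stack, nrow = ns)
  for (s in seq_len(ns)) m[s, ] <- as.numeric(fields[[s]]$densities)
  stack <- array(m, dim = c(ns, d0))
  if (is.null(roi_mask)) roi_mask <- array(TRUE, dim = d0[1:3])
  if (!identical(dim(roi_mask), d0[1:3]))
    stop("cohort_fodf: roi_mask grid does not match the fODF grid")
  if (is.null(subject_ids)) subject_ids <- sprintf("sub-%02d", seq_len(ns))
  structure(list(stack = stack, roi_mask = array(as.logical(roi_mask),
                                                 dim = d0[1:3]),
                 affine = a0, directions = fields[[1]]$directions,
                 subject_ids = subject_ids),
            class = "cohort_fodf")
}

#' @export
print.cohort_fodf <- function(x, ...) {
  d <- dim(x$stack)
  cat(sprintf("<cohort_fodf> %d subjects, grid %dx%dx%d, %d directions\n",
              d[1], d[2], d[3], d[4], d[5]))
  cat(sprintf("  ROI mask: %d voxels\n", sum(x$roi_mask)))
  invisible(x)
}

#' Extract one subject's field from a cohort
#'
#' @param cohort a [cohort_fodf()].
#' @param subject subject index (1-based).
#' @return an [fodf_field()].
#' @export
cohort_subject <- function(cohort, subject) {
  stopifnot(inherits(cohort, "cohort_fodf"))
  d <- dim(cohort$stack)
  s <- as.integer(subject)
  if (s < 1L || s > d[1]) stop("cohort_subject: subject index out of range")
  m <- matrix(cohort$stack, nrow = d[1])
  fodf_field(array(m[s, ], dim = d[-1]), affine = cohort$affine,
             directions = cohort$directions)
}

# linear cell indices (voxel-major, then direction) for mask voxels
.mask_cells <- function(mask, ndir) {
  vox <- which(mask)
  nvox <- length(mask)
  rep(vox, times = ndir) + rep((seq_len(ndir) - 1L) * nvox,
                               each = length(vox))
}

#' Cross-subject standard deviation of orientation densities
#'
#' For every direction `d` (and, in `"voxelwise"` mode, every ROI voxel),
#' computes the sample standard deviation (ddof = 1) of the fODF density
#' across subjects.  Low values mark orientations whose density is
#' consistent across the cohort — the signature of a real fiber population
#' — while orientations dominated by noise vary across subjects and score
#' high.
#'
#' Two voxel-correspondence conventions are supported: `"voxelwise"`
#' (default) treats grids as pre-aligned and computes sigma per
#' `(voxel, direction)` cell; `"roi_pooled"` pools all ROI voxels of all
#' subjects and computes one sigma per direction.
#'
#' @param cohort a [cohort_fodf()] with >= 2 subjects.
#' @param mode `"voxelwise"` or `"roi_pooled"`.
#' @return An object of class `std_field`: list with `sigma` (4-D array,
#'   `NA` outside the ROI mask), `mode`, `ddof` (always 1), `roi_mask`.
#' @export
cross_subject_std <- function(cohort, mode = c("voxelwise", "roi_pooled")) {
  stopifnot(inherits(cohort, "cohort_fodf"))
  mode <- match.arg(mode)
  d <- dim(cohort$stack)
  ns <- d[1]
  if (ns < 2L) stop("cross_subject_std: need >= 2 subjects", call. = FALSE)
  ndir <- d[5]
  grid <- d[2:4]
  cells <- .mask_cells(cohort$roi_mask, ndir)
  m <- matrix(cohort$stack, nrow = ns)[, cells, drop = FALSE]
  sigma <- array(NA_real_, dim = c(grid, ndir))
  if (mode == "voxelwise") {
    mu <- colMeans(m)
    ss <- colSums(m^2)
    v <- (ss - ns * mu^2) / (ns - 1)
    v[v < 0] <- 0
    sigma[cells] <- sqrt(v)
  } else {
    nmask <- sum(cohort$roi_mask)
    pooled <- matrix(m, nrow = ns * nmask)   # columns = directions
    n <- ns * nmask
    mu <- colMeans(pooled)
    ss <- colSums(pooled^2)
    v <- (ss - n * mu^2) / (n - 1)
    v[v < 0] <- 0
    sigma[cells] <- rep(sqrt(v), each = nmask)
  }
  structure(list(sigma = sigma, mode = mode, ddof = 1L,
                 roi_mask = cohort$roi_mask),
            class = "std_field")
}

#' @export
print.std_field <- function(x, ...) {
  cat(sprintf("<std_field> mode '%s' (ddof = %d), %d ROI voxels\n",
              x$mode, x$ddof, sum(x$roi_mask)))
  cat(sprintf("  sigma range in ROI: [%.4g, %.4g]\n",
              min(x$sigma, na.rm = TRUE), max(x$sigma, na.rm = TRUE)))
  invisible(x)
}

#' Default division guard for reweighting
#'
#' `1e-8` times the median sigma over the ROI: scale-free, and only there
#' to keep cells where all subjects agree exactly from dividing by zero.
#'
#' @param sigma a `std_field`.
#' @return nonnegative scalar.
#' @export
reweight_epsilon <- function(sigma) {
  med <- stats::median(sigma$sigma, na.rm = TRUE)
  1e-8 * med
}

#' Reweight one subject's fODF by the cross-subject standard deviation
#'
#' Inside the ROI mask, each density is divided by its cross-subject
#' standard deviation (plus a small guard `epsilon`):
#' `out(v, d) = in(v, d) / (sigma(v, d) + epsilon)`.  Voxels outside the
#' mask pass through unchanged.  The stored output is deliberately *not*
#' renormalized; probability normalization happens only in
#' [fodf_to_pmf()] at tracking time.
#'
#' @param subject_fodf an [fodf_field()].
#' @param sigma a `std_field` from [cross_subject_std()] on the same grid.
#' @param epsilon nonnegative guard added to sigma before division
#'   (default [reweight_epsilon()]).
#' @return an [fodf_field()] with reweighted densities.
#' @export
reweight_fodf <- function(subject_fodf, sigma, epsilon = NULL) {
  stopifnot(inherits(subject_fodf, "fodf_field"),
            inherits(sigma, "std_field"))
  d <- dim(subject_fodf$densities)
  if (!identical(d, dim(sigma$sigma)))
    stop("reweight_fodf: fODF and sigma grids do not match")
  if (is.null(epsilon)) epsilon <- reweight_epsilon(sigma)
  if (epsilon < 0) stop("reweight_fodf: epsilon must be >= 0")
  cells <- .mask_cells(sigma$roi_mask, d[4])
  sig <- sigma$sigma[cells]
  if (epsilon == 0 && any(sig == 0)) {
    bad <- cells[which(sig == 0)[1]]
    vox <- arrayInd(((bad - 1L) %% prod(d[1:3])) + 1L, d[1:3])
    stop(sprintf(paste0("reweight_fodf: sigma = 0 at voxel (%d, %d, %d) ",
                        "with epsilon = 0; use a positive guard"),
                 vox[1], vox[2], vox[3]), call. = FALSE)
  }
  out <- subject_fodf$densities
  out[cells] <- out[cells] / (sig + epsilon)
  f <- fodf_field(out, affine = subject_fodf$affine,
                  directions = subject_fodf$directions)
  f$reweight <- list(epsilon = epsilon, mode = sigma$mode)
  f
}

#' Reweight every subject of a cohort
#'
#' Convenience wrapper: computes [cross_subject_std()] on the cohort's ROI
#' and applies [reweight_fodf()] to each subject, returning a new cohort.
#'
#' @param cohort a [cohort_fodf()].
#' @param mode sigma convention, see [cross_subject_std()].
#' @param epsilon division guard (default [reweight_epsilon()]).
#' @return a list with `cohort` (the reweighted [cohort_fodf()]) and
#'   `sigma` (the `std_field` used).
#' @export
reweight_cohort <- function(cohort, mode = "voxelwise", epsilon = NULL) {
  sigma <- cross_subject_std(cohort, mode = mode)
  if (is.null(epsilon)) epsilon <- reweight_epsilon(sigma)
  d <- dim(cohort$stack)
  cells <- .mask_cells(cohort$roi_mask, d[5])
  sig <- sigma$sigma[cells]
  if (epsilon == 0 && any(sig == 0))
    stop("reweight_cohort: sigma = 0 inside the ROI with epsilon = 0")
  m <- matrix(cohort$stack, nrow = d[1])
  m[, cells] <- m[, cells] / rep(sig + epsilon, each = d[1])
  out <- cohort
  out$stack <- array(m, dim = d)
  list(cohort = out, sigma = sigma, epsilon = epsilon)
}

#' Medial-lateral band mass fraction of an fODF field
#'
#' The fraction of total orientation density, over the ROI voxels, carried
#' by directions whose axial orientation angle is within `90 - phi_min`
#' degrees of the medial-lateral axis (`|phi| > phi_min`).  Directions with
#' undefined phi are excluded from both numerator and denominator.
#'
#' @param f an [fodf_field()].
#' @param roi_mask logical 3-D array (default: whole grid).
#' @param phi_min band threshold in degrees (default 81, i.e. the 10% of
#'   axial angles nearest the M-L axis).
#' @return scalar fraction in `[0, 1]`.
#' @export
band_mass_fraction <- function(f, roi_mask = NULL, phi_min = 81) {
  stopifnot(inherits(f, "fodf_field"))
  d <- dim(f$densities)
  if (is.null(roi_mask)) roi_mask <- array(TRUE, dim = d[1:3])
  ang <- orientation_angles(f$directions)
  keep <- ang$defined
  band <- keep & abs(ang$phi) > phi_min
  cells_all <- .mask_cells(roi_mask, d[4])
  sel <- matrix(f$densities[cells_all], ncol = d[4])
  total <- sum(sel[, keep])
  if (total <= 0) return(NA_real_)
  sum(sel[, band]) / total
}

# ---- orientation-angle change histograms ---------------------------------

#' Orientation-angle histogram of reweighting-induced fODF changes
#'
#' Quantifies *where on the sphere* reweighting adds and removes
#' probability.  Per subject: (1) each ROI voxel's densities are
#' normalized to probabilities in both fields; (2) reweighted minus
#' original differences are split into a positive and a negative pool;
#' (3) the median of each pool is the threshold; (4) directions with
#' above-median increases, and separately directions with below-median
#' (most negative) decreases, contribute their orientation angle phi to a
#' 20-bin histogram on `[-90, 90]` degrees; (5) bin counts are averaged
#' across subjects.  Directions with undefined phi are excluded with a
#' logged count.  An empty pool yields an all-zero histogram and a flag,
#' not an error.
#'
#' @param before,after single [fodf_field()]s or equal-length lists of
#'   them (one per subject), on identical grids and direction sets.
#' @param roi_mask logical 3-D array restricting pooling (default: whole
#'   grid).
#' @param n_bins number of equal bins on `[-90, 90]` (default 20).
#' @return An object of class `change_histogram`: list with `bin_edges`
#'   (length `n_bins + 1`), `increase_counts`, `decrease_counts`
#'   (per-bin means across subjects), `per_subject_medians` (data frame
#'   with `increase` and `decrease` thresholds), `n_undefined_excluded`,
#'   and `flags` (per subject: `empty_increase`, `empty_decrease`).
#' @export
change_histogram <- function(before, after, roi_mask = NULL, n_bins = 20L) {
  if (inherits(before, "fodf_field")) before <- list(before)
  if (inherits(after, "fodf_field")) after <- list(after)
  if (length(before) != length(after))
    stop("change_histogram: 'before' and 'after' must have equal length")
  ns <- length(before)
  d <- dim(before[[1]]$densities)
  if (is.null(roi_mask)) roi_mask <- array(TRUE, dim = d[1:3])
  ang <- orientation_angles(before[[1]]$directions)
  edges <- seq(-90, 90, length.out = n_bins + 1L)
  inc <- matrix(0, ns, n_bins)
  dec <- matrix(0, ns, n_bins)
  med_inc <- med_dec <- rep(NA_real_, ns)
  empty_inc <- empty_dec <- logical(ns)
  cells <- .mask_cells(roi_mask, d[4])
  n_undef <- 0L
  for (s in seq_len(ns)) {
    if (!identical(dim(after[[s]]$densities), d))
      stop("change_histogram: field grids do not match")
    b <- matrix(before[[s]]$densities[cells], ncol = d[4])
    a <- matrix(after[[s]]$densities[cells], ncol = d[4])
    b[b < 0] <- 0; a[a < 0] <- 0
    bs <- rowSums(b); as_ <- rowSums(a)
    ok <- bs > 0 & as_ > 0
    b <- b[ok, , drop = FALSE] / bs[ok]
    a <- a[ok, , drop = FALSE] / as_[ok]
    diff <- a - b
    phi_cell <- matrix(ang$phi, nrow = nrow(diff), ncol = d[4], byrow = TRUE)
    def_cell <- matrix(ang$defined, nrow = nrow(diff), ncol = d[4],
                       byrow = TRUE)
    pos <- diff > 0
    neg <- diff < 0
    if (any(pos)) {
      med_inc[s] <- stats::median(diff[pos])
      sel <- pos & diff > med_inc[s]
      n_undef <- n_undef + sum(sel & !def_cell)
      ph <- phi_cell[sel & def_cell]
      if (length(ph))
        inc[s, ] <- tabulate(.phi_bin(ph, edges), nbins = n_bins)
    } else empty_inc[s] <- TRUE
    if (any(neg)) {
      med_dec[s] <- stats::median(diff[neg])
      sel <- neg & diff < med_dec[s]
      n_undef <- n_undef + sum(sel & !def_cell)
      ph <- phi_cell[sel & def_cell]
      if (length(ph))
        dec[s, ] <- tabulate(.phi_bin(ph, edges), nbins = n_bins)
    } else empty_dec[s] <- TRUE
  }
  structure(list(bin_edges = edges,
                 increase_counts = colMeans(inc),
                 decrease_counts = colMeans(dec),
                 per_subject_medians = data.frame(increase = med_inc,
                                                  decrease = med_dec),
                 n_undefined_excluded = n_undef,
                 flags = data.frame(empty_increase = empty_inc,
                                    empty_decrease = empty_dec)),
            class = "change_histogram")
}

.phi_bin <- function(phi, edges) {
  findInterval(phi, edges, rightmost.closed = TRUE, all.inside = TRUE)
}

#' @export
print.change_histogram <- function(x, ...) {
  nb <- length(x$increase_counts)
  cat(sprintf("<change_histogram> %d bins on [-90, 90] deg\n", nb))
  mid <- (x$bin_edges[-1] + x$bin_edges[-(nb + 1)]) / 2
  if (sum(x$increase_counts) > 0)
    cat(sprintf("  modal increase bin: [%g, %g] deg\n",
                x$bin_edges[which.max(x$increase_counts)],
                x$bin_edges[which.max(x$increase_counts) + 1]))
  if (sum(x$decrease_counts) > 0)
    cat(sprintf("  modal decrease bin: [%g, %g] deg\n",
                x$bin_edges[which.max(x$decrease_counts)],
                x$bin_edges[which.max(x$decrease_counts) + 1]))
  if (any(x$flags$empty_increase) || any(x$flags$empty_decrease))
    cat("  note: empty difference pool in at least one subject\n")
  invisible(x)
}

#' @export
plot.change_histogram <- function(x, ...) {
  nb <- length(x$increase_counts)
  mid <- (x$bin_edges[-1] + x$bin_edges[-(nb + 1)]) / 2
  old <- graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(old))
  graphics::barplot(x$increase_counts, names.arg = round(mid),
                    main = "above-median increase", xlab = "phi (deg)",
                    ylab = "mean count", ...)
  graphics::barplot(x$decrease_counts, names.arg = round(mid),
                    main = "below-median decrease", xlab = "phi (deg)",
                    ylab = "mean count", ...)
  invisible(x)
}

#' Write a change histogram as TSV (+ JSON sidecar)
#'
#' TSV columns: `bin_low`, `bin_high`, `increase_mean_count`,
#' `decrease_mean_count`.  The JSON sidecar carries per-subject medians,
#' pool flags and the undefined-angle exclusion count.
#'
#' @param h a [change_histogram()].
#' @param path TSV output path; the sidecar is `<path>.json`.
#' @return `path`, invisibly.
#' @export
write_change_histogram <- function(h, path) {
  stopifnot(inherits(h, "change_histogram"))
  nb <- length(h$increase_counts)
  df <- data.frame(bin_low = h$bin_edges[-(nb + 1)],
                   bin_high = h$bin_edges[-1],
                   increase_mean_count = h$increase_counts,
                   decrease_mean_count = h$decrease_counts)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(list(per_subject_medians = h$per_subject_medians,
                            n_undefined_excluded = h$n_undefined_excluded,
                            flags = h$flags),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}
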