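#' Parameters of the crossing-fiber phantom
#'
#' The phantom emulates the statistical structure of a deep white-matter
#' crossing region in which tractography misses a weak medial-lateral
#' pathway: a dominant anterior-posterior (A-P, +y) bundle throughout the
#' WM slab, a much weaker medial-lateral (M-L, +x) bundle confined to a
#' corridor connecting a medial seed wall to a lateral target wall and
#' *consistent across subjects*, and noise with two parts — spurious
#' orientation kernels at axes drawn independently per voxel and subject
#' (direction-structured noise that never repeats across the cohort) and
#' a truncated-Gaussian density floor.
#' Bundle amplitudes carry per-subject multiplicative jitter (`amp_cv`),
#' the anatomical variability that makes the cross-subject standard
#' deviation scale with bundle strength; without it the dominant A-P peak
#' would be exactly as consistent as the faint M-L peak and
#' variance-reweighting could not rebalance them.
#'
#' @param grid_shape integer 3-vector (default `c(24, 24, 12)`).
#' @param voxel_size_mm isotropic voxel edge (default 1).
#' @param a_ap A-P bundle amplitude: its total orientation mass relative
#'   to a unit-mean kernel (default 1).
#' @param a_ml M-L bundle amplitude inside the corridor (default 0.15).
#' @param kappa Watson-kernel concentration (default 20).
#' @param noise_sd per-direction additive noise scale tau; the floor is
#'   `max(N(0, tau), 0)` per (voxel, direction) (default 0.15).
#' @param n_noise_kernels spurious random-axis kernels per voxel and
#'   subject (default 3).
#' @param noise_kernel_max upper bound of the uniform amplitude of each
#'   spurious kernel (default 0.3).
#' @param amp_cv coefficient of variation of the per-subject bundle
#'   amplitude factors (default 0.1).
#' @param n_subjects cohort size (default 20, >= 2).
#' @param master_seed integer; all randomness derives from
#'   `(master_seed, subject_index)`.
#' @return An object of class `phantom_params` (validated list).
#' @export
phantom_params <- function(grid_shape = c(24L, 24L, 12L),
                           voxel_size_mm = 1,
                           a_ap = 1, a_ml = 0.15, kappa = 20,
                           noise_sd = 0.15,
                           n_noise_kernels = 3L, noise_kernel_max = 0.3,
                           amp_cv = 0.1,
                           n_subjects = 20L, master_seed = 1L) {
  grid_shape <- as.integer(grid_shape)
  if (length(grid_shape) == 1L) grid_shape <- rep(grid_shape, 3L)
  stopifnot(length(grid_shape) == 3L, all(grid_shape >= 8L),
            voxel_size_mm > 0,
            a_ap >= 0, a_ml >= 0, kappa > 0, noise_sd >= 0,
            n_noise_kernels >= 0, noise_kernel_max >= 0, amp_cv >= 0,
            n_subjects >= 2L)
  structure(list(grid_shape = grid_shape, voxel_size_mm = voxel_size_mm,
                 a_ap = a_ap, a_ml = a_ml, kappa = kappa,
                 noise_sd = noise_sd,
                 n_noise_kernels = as.integer(n_noise_kernels),
                 noise_kernel_max = noise_kernel_max,
                 amp_cv = amp_cv,
                 n_subjects = as.integer(n_subjects),
                 master_seed = as.integer(master_seed)),
            class = "phantom_params")
}

#' @export
print.phantom_params <- function(x, ...) {
  cat(sprintf(paste0("<phantom_params> grid %dx%dx%d, %d subjects, ",
                     "a_AP=%g a_ML=%g kappa=%g tau=%g\n"),
              x$grid_shape[1], x$grid_shape[2], x$grid_shape[3],
              x$n_subjects, x$a_ap, x$a_ml, x$kappa, x$noise_sd))
  invisible(x)
}

# Watson-type antipodally symmetric kernel on the direction set,
# normalized to unit mean so amplitudes are total orientation mass.
.watson_kernel <- function(dirs, axis, kappa) {
  t2 <- (unclass(dirs) %*% axis)^2
  k <- exp(kappa * (t2 - 1))
  as.numeric(k / mean(k))
}

# Fixed phantom geometry on a grid: CSF shell, GM walls at low/high x,
# WM slab between them, and an M-L corridor box through the slab.
.phantom_geometry <- function(params) {
  g <- params$grid_shape
  nx <- g[1]; ny <- g[2]; nz <- g[3]
  ix <- seq_len(nx); iy <- seq_len(ny); iz <- seq_len(nz)
  x_wm <- 4:(nx - 3)
  x_gm_med <- 2:3
  x_gm_lat <- (nx - 2):(nx - 1)
  y_in <- 3:(ny - 2)
  z_in <- 2:(nz - 1)
  y_cor <- max(3, floor(ny / 2) - 3):min(ny - 2, floor(ny / 2) + 4)
  z_cor <- max(2, floor(nz / 2) - 2):min(nz - 1, floor(nz / 2) + 3)
  wm <- array(FALSE, g);  wm[x_wm, y_in, z_in] <- TRUE
  gm <- array(FALSE, g)
  gm[x_gm_med, y_in, z_in] <- TRUE
  gm[x_gm_lat, y_in, z_in] <- TRUE
  csf <- !(wm | gm)
  corridor <- array(FALSE, g); corridor[x_wm, y_cor, z_cor] <- TRUE
  seed_roi <- array(FALSE, g); seed_roi[x_wm[1], y_cor, z_cor] <- TRUE
  target_lateral <- array(FALSE, g)
  target_lateral[x_gm_lat, y_cor, z_cor] <- TRUE
  mid <- x_wm[floor(length(x_wm) / 2) + c(0L, 1L)]
  target_path <- array(FALSE, g); target_path[mid, y_cor, z_cor] <- TRUE
  affine <- diag(c(rep(params$voxel_size_mm, 3), 1))
  # corridor voxels first, so the noise stream of a corridor-restricted
  # generation is a prefix of the full-volume stream (bit-identical values)
  wm_idx <- c(which(wm & corridor), which(wm & !corridor))
  list(wm = wm, gm = gm, csf = csf, corridor = corridor,
       seed_roi = seed_roi, target_lateral = target_lateral,
       target_path = target_path, affine = affine,
       wm_idx = wm_idx,
       w = as.numeric(corridor[wm_idx]),
       bbox = list(x = range(which(apply(corridor, 1, any))),
                   y = range(which(apply(corridor, 2, any))),
                   z = range(which(apply(corridor, 3, any)))))
}

# per-subject seeds derived from the master seed
.subject_seeds <- function(params) {
  set.seed(params$master_seed)
  sample.int(.Machine$integer.max - 1L, params$n_subjects)
}

# WM-voxel x direction density matrix for one subject.  Spurious noise
# kernels are drawn per (voxel, kernel) — spurious fODF peaks in real
# data vary from voxel to voxel as well as across subjects.  Every
# random block (amplitude factors, kernel axes, kernel amplitudes, noise
# floor) uses its own sub-stream of the subject seed and is drawn
# voxel-major with corridor voxels first, so a generation restricted to
# the first `n_keep` voxels consumes a prefix of each stream and
# reproduces those voxels bit-identically.
.phantom_subject_wm <- function(params, geom, dirs, subj_seed,
                                n_keep = length(geom$wm_idx)) {
  ndir <- attr(dirs, "n")
  V <- unclass(dirs)
  k_ap <- .watson_kernel(dirs, c(0, 1, 0), params$kappa)
  k_ml <- .watson_kernel(dirs, c(1, 0, 0), params$kappa)
  set.seed(subj_seed)
  sub_seeds <- sample.int(.Machine$integer.max - 1L, 4L)
  set.seed(sub_seeds[1])
  g_ap <- max(stats::rnorm(1, 1, params$amp_cv), 0.05)
  g_ml <- max(stats::rnorm(1, 1, params$amp_cv), 0.05)
  w <- geom$w[seq_len(n_keep)]
  base <- params$a_ap * g_ap * k_ap
  mat_t <- outer(params$a_ml * g_ml * k_ml, w) + base   # ndir x n_keep
  nk <- params$n_noise_kernels
  if (nk > 0 && params$noise_kernel_max > 0) {
    set.seed(sub_seeds[2])
    axes <- matrix(stats::rnorm(3L * nk * n_keep), nrow = 3L)
    axes <- axes / rep(sqrt(colSums(axes^2)), each = 3L)
    set.seed(sub_seeds[3])
    amps <- stats::runif(nk * n_keep, 0, params$noise_kernel_max)
    kk <- exp(params$kappa * ((t(axes) %*% t(V))^2 - 1))  # (nk*n_keep) x ndir
    kk <- kk * (amps / rowMeans(kk))
    mat_t <- mat_t + t(rowsum(kk, rep(seq_len(n_keep), each = nk),
                              reorder = FALSE))
  }
  if (params$noise_sd > 0) {
    set.seed(sub_seeds[4])
    eps <- stats::rnorm(n_keep * ndir, 0, params$noise_sd)
    eps[eps < 0] <- 0
    mat_t <- mat_t + eps
  }
  t(mat_t)
}

#' Generate one phantom subject
#'
#' Per WM voxel, the orientation density is
#' `a_AP * g_AP * K(d; y) + a_ML * g_ML * w(v) * K(d; x) + sum_k a_k * K(d; axis_k) + eps(v, d)`,
#' where `K` is an antipodally symmetric Watson kernel (unit mean over the
#' direction set), `g_AP`/`g_ML` are the subject's amplitude factors,
#' `w(v)` marks the M-L corridor, the spurious kernels have
#' subject-specific random axes and amplitudes, and `eps` is
#' truncated-at-zero Gaussian noise with scale `noise_sd`.  All randomness
#' derives from `(master_seed, subject_index)`.
#'
#' @param params a [phantom_params()].
#' @param subject_index 1-based subject index.
#' @param directions the shared [direction_set()] (default
#'   [default_sphere()]).
#' @return An object of class `phantom_bundle`: list with `fodf`
#'   ([fodf_field()]), `tissue` ([tissue_maps()]), `masks` (list of
#'   logical arrays: `seed_roi`, `target_lateral`, `target_path`,
#'   `deep_wm`, `wm`), `truth` (the noiseless density field as an
#'   [fodf_field()]), `subject_index`, `params`.
#' @export
generate_subject <- function(params, subject_index,
                             directions = default_sphere()) {
  stopifnot(inherits(params, "phantom_params"),
            subject_index >= 1L, subject_index <= params$n_subjects)
  geom <- .phantom_geometry(params)
  seeds <- .subject_seeds(params)
  mat <- .phantom_subject_wm(params, geom, directions, seeds[subject_index])
  ndir <- attr(directions, "n")
  dens <- array(0, dim = c(params$grid_shape, ndir))
  cells <- rep(geom$wm_idx, times = ndir) +
    rep((seq_len(ndir) - 1L) * prod(params$grid_shape),
        each = length(geom$wm_idx))
  dens[cells] <- mat
  truth <- array(0, dim = c(params$grid_shape, ndir))
  k_ap <- .watson_kernel(directions, c(0, 1, 0), params$kappa)
  k_ml <- .watson_kernel(directions, c(1, 0, 0), params$kappa)
  truth[cells] <- matrix(params$a_ap * k_ap, nrow = length(geom$wm_idx),
                         ncol = ndir, byrow = TRUE) +
    outer(geom$w, params$a_ml * k_ml)
  structure(list(fodf = fodf_field(dens, affine = geom$affine,
                                   directions = directions),
                 tissue = tissue_maps(gm = geom$gm * 1, wm = geom$wm * 1,
                                      csf = geom$csf * 1,
                                      affine = geom$affine),
                 masks = list(seed_roi = geom$seed_roi,
                              target_lateral = geom$target_lateral,
                              target_path = geom$target_path,
                              deep_wm = geom$corridor,
                              wm = geom$wm),
                 truth = fodf_field(truth, affine = geom$affine,
                                    directions = directions),
                 subject_index = as.integer(subject_index),
                 params = params),
            class = "phantom_bundle")
}

#' @export
print.phantom_bundle <- function(x, ...) {
  cat(sprintf("<phantom_bundle> subject %d of %d\n",
              x$subject_index, x$params$n_subjects))
  print(x$fodf)
  invisible(x)
}

#' Generate a phantom cohort
#'
#' `n_subjects` calls of the per-subject generator on a shared grid: the
#' A-P bundle and the M-L corridor are identical across subjects (up to
#' amplitude jitter); spurious kernels and the noise floor are
#' independent.  Cohort generation is a pure function of the parameters.
#'
#' @param params a [phantom_params()].
#' @param directions the shared [direction_set()].
#' @param region `"full"` (default) generates the whole volume;
#'   `"corridor"` generates only the M-L corridor box on a cropped grid
#'   — bit-identical densities to the corridor voxels of the full
#'   volume, at a fraction of the cost.  The cropped cohort is intended
#'   for fODF-level statistics (sigma, reweighting, band fractions,
#'   change histograms); tracking needs the full volume.
#' @return An object of class `phantom_cohort`: list with `cohort` (a
#'   [cohort_fodf()] whose ROI mask is the M-L corridor), `tissue`,
#'   `masks`, `truth` (noiseless [fodf_field()]), `params`.
#' @export
generate_cohort <- function(params, directions = default_sphere(),
                            region = c("full", "corridor")) {
  stopifnot(inherits(params, "phantom_params"))
  region <- match.arg(region)
  geom <- .phantom_geometry(params)
  seeds <- .subject_seeds(params)
  ndir <- attr(directions, "n")
  ns <- params$n_subjects
  if (region == "corridor") return(.corridor_cohort(params, directions,
                                                    geom, seeds))
  nvox <- prod(params$grid_shape)
  stack <- matrix(0, nrow = ns, ncol = nvox * ndir)
  cells <- rep(geom$wm_idx, times = ndir) +
    rep((seq_len(ndir) - 1L) * nvox, each = length(geom$wm_idx))
  for (s in seq_len(ns))
    stack[s, cells] <- .phantom_subject_wm(params, geom, directions, seeds[s])
  dim(stack) <- c(ns, params$grid_shape, ndir)
  cohort <- structure(list(stack = stack,
                           roi_mask = geom$corridor,
                           affine = geom$affine,
                           directions = directions,
                           subject_ids = sprintf("phantom-%02d", seq_len(ns))),
                      class = "cohort_fodf")
  truth <- array(0, dim = c(params$grid_shape, ndir))
  k_ap <- .watson_kernel(directions, c(0, 1, 0), params$kappa)
  k_ml <- .watson_kernel(directions, c(1, 0, 0), params$kappa)
  truth[cells] <- matrix(params$a_ap * k_ap, nrow = length(geom$wm_idx),
                         ncol = ndir, byrow = TRUE) +
    outer(geom$w, params$a_ml * k_ml)
  structure(list(cohort = cohort,
                 tissue = tissue_maps(gm = geom$gm * 1, wm = geom$wm * 1,
                                      csf = geom$csf * 1,
                                      affine = geom$affine),
                 masks = list(seed_roi = geom$seed_roi,
                              target_lateral = geom$target_lateral,
                              target_path = geom$target_path,
                              deep_wm = geom$corridor,
                              wm = geom$wm),
                 truth = fodf_field(truth, affine = geom$affine,
                                    directions = directions),
                 params = params),
            class = "phantom_cohort")
}

# corridor-restricted cohort on the cropped corridor bounding box; the
# corridor is a box, so the cropped grid is exactly the corridor and the
# noise-stream prefix property makes densities bit-identical to the full
# volume's corridor voxels
.corridor_cohort <- function(params, directions, geom, seeds) {
  ndir <- attr(directions, "n")
  ns <- params$n_subjects
  bb <- geom$bbox
  gshape <- c(diff(bb$x), diff(bb$y), diff(bb$z)) + 1L
  ncor <- sum(geom$corridor)
  stopifnot(prod(gshape) == ncor)
  stack <- matrix(0, nrow = ns, ncol = ncor * ndir)
  for (s in seq_len(ns))
    stack[s, ] <- .phantom_subject_wm(params, geom, directions, seeds[s],
                                      n_keep = ncor)
  dim(stack) <- c(ns, gshape, ndir)
  affine <- geom$affine
  affine[1:3, 4] <- affine[1:3, 4] +
    affine[1:3, 1:3] %*% (c(bb$x[1], bb$y[1], bb$z[1]) - 1)
  crop <- function(m) m[bb$x[1]:bb$x[2], bb$y[1]:bb$y[2],
                        bb$z[1]:bb$z[2], drop = FALSE]
  cohort <- structure(list(stack = stack,
                           roi_mask = crop(geom$corridor),
                           affine = affine, directions = directions,
                           subject_ids = sprintf("phantom-%02d",
                                                 seq_len(ns))),
                      class = "cohort_fodf")
  k_ap <- .watson_kernel(directions, c(0, 1, 0), params$kappa)
  k_ml <- .watson_kernel(directions, c(1, 0, 0), params$kappa)
  truth <- array(rep(params$a_ap * k_ap + params$a_ml * k_ml, each = ncor),
                 dim = c(gshape, ndir))
  structure(list(cohort = cohort,
                 tissue = tissue_maps(gm = crop(geom$gm) * 1,
                                      wm = crop(geom$wm) * 1,
                                      csf = crop(geom$csf) * 1,
                                      affine = affine),
                 masks = list(seed_roi = crop(geom$seed_roi),
                              target_lateral = crop(geom$target_lateral),
                              target_path = crop(geom$target_path),
                              deep_wm = crop(geom$corridor),
                              wm = crop(geom$wm)),
                 truth = fodf_field(truth, affine = affine,
                                    directions = directions),
                 params = params),
            class = "phantom_cohort")
}

#' @export
print.phantom_cohort <- function(x, ...) {
  cat(sprintf("<phantom_cohort> %d subjects on grid %dx%dx%d\n",
              x$params$n_subjects, x$params$grid_shape[1],
              x$params$grid_shape[2], x$params$grid_shape[3]))
  cat(sprintf("  corridor (reweighting ROI): %d voxels; seed ROI: %d voxels\n",
              sum(x$masks$deep_wm), sum(x$masks$seed_roi)))
  invisible(x)
}
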