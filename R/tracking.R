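#' Tissue fraction maps for anatomically constrained stopping
#'
#' Gray-matter, white-matter and CSF fraction volumes on the fODF grid.
#' Per voxel the three fractions must not exceed 1 (tolerance 1e-6).
#' Streamlines terminate (validly) where the interpolated GM fraction
#' exceeds the stopping threshold and are discarded where the CSF
#' fraction does.
#'
#' @param gm,wm,csf numeric 3-D arrays of fractions in `[0, 1]` on a
#'   shared grid.
#' @param affine 4x4 voxel-to-world matrix.
#' @return An object of class `tissue_maps`.
#' @export
tissue_maps <- function(gm, wm, csf, affine = diag(4)) {
  stopifnot(identical(dim(gm), dim(wm)), identical(dim(gm), dim(csf)))
  if (any(gm < 0 | wm < 0 | csf < 0))
    stop("tissue_maps: fractions must be nonnegative")
  if (any(gm + wm + csf > 1 + 1e-6))
    stop("tissue_maps: gm + wm + csf exceeds 1 in some voxel")
  structure(list(gm = gm, wm = wm, csf = csf,
                 affine = as.matrix(affine)),
            class = "tissue_maps")
}

#' Streamline propagation parameters
#'
#' @param step_size_mm step length; `NULL` (default) resolves to half the
#'   smallest voxel edge at tracking time.
#' @param max_angle_deg maximum turning angle between consecutive steps;
#'   candidate directions outside this cone around the incoming direction
#'   are inadmissible (default 30).
#' @param seeds_per_voxel random seeding locations per seed-mask voxel
#'   (default 6).
#' @param max_steps per-direction step budget (default 1000).
#' @param mode `"probabilistic"` (sample the next direction from the
#'   voxel's fODF probabilities restricted to the admissible cone) or
#'   `"deterministic"` (follow the largest admissible density).
#' @param rng_seed integer seed controlling seeding locations and
#'   probabilistic sampling.
#' @param gm_stop,csf_stop tissue-fraction stopping thresholds
#'   (defaults 0.5).
#' @return An object of class `tracking_params`.
#' @export
tracking_params <- function(step_size_mm = NULL, max_angle_deg = 30,
                            seeds_per_voxel = 6L, max_steps = 1000L,
                            mode = c("probabilistic", "deterministic"),
                            rng_seed = 1L, gm_stop = 0.5, csf_stop = 0.5) {
  mode <- match.arg(mode)
  stopifnot(is.null(step_size_mm) || step_size_mm > 0,
            max_angle_deg > 0, max_angle_deg < 90,
            seeds_per_voxel >= 1L, max_steps >= 1L)
  structure(list(step_size_mm = step_size_mm,
                 max_angle_deg = max_angle_deg,
                 seeds_per_voxel = as.integer(seeds_per_voxel),
                 max_steps = as.integer(max_steps), mode = mode,
                 rng_seed = as.integer(rng_seed),
                 gm_stop = gm_stop, csf_stop = csf_stop),
            class = "tracking_params")
}

#' Random seeding locations inside a mask
#'
#' Draws `seeds_per_voxel` uniformly distributed points inside every mask
#' voxel (reproducibly from `rng_seed`) and maps them to world
#' coordinates.
#'
#' @param mask logical 3-D array.
#' @param params a [tracking_params()].
#' @param affine 4x4 voxel-to-world matrix of the mask grid.
#' @return numeric matrix (n x 3) of world points, with attribute `voxel`
#'   (1-based linear voxel index of each seed).
#' @export
seed_points <- function(mask, params, affine = diag(4)) {
  stopifnot(inherits(params, "tracking_params"))
  vox <- which(mask)
  if (length(vox) == 0L) stop("seed_points: empty seed mask")
  set.seed(params$rng_seed)
  k <- params$seeds_per_voxel
  idx <- rep(vox, each = k)
  ijk0 <- arrayInd(idx, dim(mask)) - 1L        # voxel centers, 0-based
  jitter <- matrix(stats::runif(length(idx) * 3L, -0.5, 0.5), ncol = 3L)
  vcoord <- ijk0 + jitter
  pts <- cbind(vcoord, 1) %*% t(as.matrix(affine))
  structure(pts[, 1:3, drop = FALSE], voxel = idx)
}

# trilinear interpolation of a 3-D volume at a 0-based continuous voxel
# coordinate; outside the grid the volume is treated as zero
.trilinear <- function(vol, c0) {
  d <- dim(vol)
  f <- floor(c0)
  t <- c0 - f
  acc <- 0
  for (dx in 0:1) for (dy in 0:1) for (dz in 0:1) {
    i <- f[1] + dx; j <- f[2] + dy; k <- f[3] + dz
    if (i < 0 || j < 0 || k < 0 || i >= d[1] || j >= d[2] || k >= d[3]) next
    w <- (if (dx) t[1] else 1 - t[1]) *
         (if (dy) t[2] else 1 - t[2]) *
         (if (dz) t[3] else 1 - t[3])
    acc <- acc + w * vol[i + 1, j + 1, k + 1]
  }
  acc
}

#' Propagate streamlines through an fODF field
#'
#' Bidirectional propagation from each seed.  The initial direction is
#' drawn from the seed voxel's fODF (argmax in deterministic mode); both
#' hemispheres of the initial axis are then tracked and concatenated.
#' Per step, the next direction must lie within `max_angle_deg` of the
#' incoming direction: deterministic mode takes the largest admissible
#' density, probabilistic mode samples the admissible directions with
#' probabilities proportional to their (floored) densities.  At each new
#' point tissue fractions are interpolated trilinearly: GM above
#' `gm_stop` terminates the half validly, CSF above `csf_stop` discards
#' the streamline, a degenerate (zero-density) fODF voxel discards it,
#' an empty admissible cone discards it for excessive curving, and
#' exhausting `max_steps` (or leaving the volume) discards it for length.
#' fODF lookup is nearest-voxel.
#'
#' @param f an [fodf_field()].
#' @param tissue a [tissue_maps()] on the same grid.
#' @param seeds world-point matrix from [seed_points()] (or any n x 3
#'   matrix of in-volume points).
#' @param params a [tracking_params()].
#' @return An object of class `streamline_set`: list with `polylines`
#'   (list of n x 3 world-coordinate matrices), `status` (factor with
#'   levels `valid_gm_termination`, `discarded_csf`, `discarded_angle`,
#'   `discarded_length`, `discarded_degenerate`), `seed_point`,
#'   `step_size_mm`, `affine`, `params`.
#' @export
propagate <- function(f, tissue, seeds, params) {
  stopifnot(inherits(f, "fodf_field"), inherits(tissue, "tissue_maps"),
            inherits(params, "tracking_params"))
  if (max(abs(f$affine - tissue$affine)) > 1e-9 ||
      !identical(dim(f$densities)[1:3], dim(tissue$gm)))
    stop("propagate: fODF and tissue grids are not aligned", call. = FALSE)
  seeds <- as.matrix(seeds)
  grid <- dim(f$densities)[1:3]
  ndir <- dim(f$densities)[4]
  V <- unclass(f$directions)
  inv <- solve(f$affine)
  step <- params$step_size_mm
  if (is.null(step)) {
    edges <- sqrt(colSums(as.matrix(f$affine)[1:3, 1:3]^2))
    step <- 0.5 * min(edges)
  }
  cthr <- cos(params$max_angle_deg * pi / 180)
  G <- V %*% t(V)
  cone <- lapply(seq_len(ndir), function(i) which(G[i, ] >= cthr))
  anti <- apply(G, 1L, which.min)          # antipode index per direction
  deterministic <- params$mode == "deterministic"
  set.seed(params$rng_seed + 1L)           # sampling stream, distinct from seeding
  dens4 <- f$densities
  to_vox0 <- function(p) (inv %*% c(p, 1))[1:3]

  track_half <- function(p, di) {
    pts <- matrix(NA_real_, params$max_steps, 3L)
    n <- 0L
    status <- "discarded_length"
    for (s in seq_len(params$max_steps)) {
      p <- p + step * V[di, ]
      c0 <- to_vox0(p)
      vox <- round(c0) + 1
      if (any(vox < 1) || any(vox > grid)) { status <- "discarded_length"; break }
      n <- n + 1L; pts[n, ] <- p
      gm_f <- .trilinear(tissue$gm, c0)
      if (gm_f > params$gm_stop) { status <- "valid_gm_termination"; break }
      if (.trilinear(tissue$csf, c0) > params$csf_stop) {
        status <- "discarded_csf"; break
      }
      w <- dens4[vox[1], vox[2], vox[3], ]
      w[w < 0] <- 0
      if (sum(w) <= 0) { status <- "discarded_degenerate"; break }
      adm <- cone[[di]]
      wa <- w[adm]
      sa <- sum(wa)
      if (sa <= 0) { status <- "discarded_angle"; break }
      di <- if (deterministic) adm[which.max(wa)]
            else adm[sample.int(length(adm), 1L, prob = wa)]
    }
    list(points = pts[seq_len(n), , drop = FALSE], status = status)
  }

  n_seed <- nrow(seeds)
  polylines <- vector("list", n_seed)
  status <- character(n_seed)
  priority <- c(discarded_csf = 1, discarded_angle = 2,
                discarded_degenerate = 3, discarded_length = 4)
  for (q in seq_len(n_seed)) {
    p0 <- seeds[q, ]
    c0 <- to_vox0(p0)
    vox <- round(c0) + 1
    if (any(vox < 1) || any(vox > grid))
      stop("propagate: seed outside the volume")
    w <- dens4[vox[1], vox[2], vox[3], ]
    w[w < 0] <- 0
    if (sum(w) <= 0) {
      polylines[[q]] <- matrix(p0, 1L, 3L)
      status[q] <- "discarded_degenerate"
      next
    }
    i0 <- if (deterministic) which.max(w)
          else sample.int(ndir, 1L, prob = w)
    # canonical hemisphere so the polyline orientation is reproducible
    v0 <- V[i0, ]
    flip <- v0[1] < 0 || (v0[1] == 0 && (v0[2] < 0 ||
                          (v0[2] == 0 && v0[3] < 0)))
    if (flip) i0 <- anti[i0]
    plus <- track_half(p0, i0)
    minus <- track_half(p0, anti[i0])
    polylines[[q]] <- rbind(minus$points[rev(seq_len(nrow(minus$points))), ,
                                         drop = FALSE],
                            matrix(p0, 1L, 3L), plus$points)
    st <- c(minus$status, plus$status)
    if (all(st == "valid_gm_termination")) {
      status[q] <- "valid_gm_termination"
    } else {
      bad <- st[st != "valid_gm_termination"]
      status[q] <- bad[order(priority[bad])][1]
    }
  }
  structure(list(polylines = polylines,
                 status = factor(status, levels = c("valid_gm_termination",
                                                    "discarded_csf",
                                                    "discarded_angle",
                                                    "discarded_length",
                                                    "discarded_degenerate")),
                 seed_point = seeds, step_size_mm = step,
                 affine = f$affine, params = params),
            class = "streamline_set")
}

#' @export
print.streamline_set <- function(x, ...) {
  cat(sprintf("<streamline_set> %d streamlines (step %.3g mm)\n",
              length(x$polylines), x$step_size_mm))
  print(table(x$status))
  invisible(x)
}

#' @export
summary.streamline_set <- function(object, ...) {
  len <- vapply(object$polylines, nrow, integer(1))
  out <- list(n = length(object$polylines),
              status = table(object$status),
              valid_fraction = mean(object$status == "valid_gm_termination"),
              length_mm = summary(len * object$step_size_mm))
  class(out) <- "summary.streamline_set"
  out
}

#' @export
print.summary.streamline_set <- function(x, ...) {
  cat(sprintf("%d streamlines, %.1f%% valid\n", x$n,
              100 * x$valid_fraction))
  print(x$status)
  cat("length (mm):\n"); print(x$length_mm)
  invisible(x)
}

#' Classify a streamline's termination
#'
#' Pure, idempotent function of the final point's interpolated tissue
#' fractions and the recorded discard trace: a CSF entry in the trace
#' discards the streamline; otherwise a GM endpoint terminates it
#' validly; otherwise the exhausted step budget (or an excessive-curving
#' or degenerate-voxel event in the trace) gives the matching discard
#' status.
#'
#' @param streamline list with `points` (n x 3 world matrix) and
#'   optionally `trace` (character vector of events among `"csf_entry"`,
#'   `"angle_violation"`, `"degenerate_voxel"`, `"max_steps"`).
#' @param tissue a [tissue_maps()].
#' @param gm_stop,csf_stop stopping thresholds.
#' @return one of the five status strings of [propagate()].
#' @export
classify_termination <- function(streamline, tissue, gm_stop = 0.5,
                                 csf_stop = 0.5) {
  trace <- streamline$trace %||% character(0)
  if ("csf_entry" %in% trace) return("discarded_csf")
  if ("angle_violation" %in% trace) return("discarded_angle")
  if ("degenerate_voxel" %in% trace) return("discarded_degenerate")
  pts <- streamline$points
  inv <- solve(tissue$affine)
  c0 <- (inv %*% c(pts[nrow(pts), ], 1))[1:3]
  if (.trilinear(tissue$gm, c0) > gm_stop) return("valid_gm_termination")
  if (.trilinear(tissue$csf, c0) > csf_stop) return("discarded_csf")
  "discarded_length"
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Fraction of valid streamlines reaching a target mask
#'
#' @param ss a `streamline_set`.
#' @param mask logical 3-D array on the tracking grid.
#' @return fraction of *valid* streamlines with at least one endpoint in
#'   a mask voxel (0 if there are no valid streamlines).
#' @export
fraction_reaching_target <- function(ss, mask) {
  stopifnot(inherits(ss, "streamline_set"))
  valid <- which(ss$status == "valid_gm_termination")
  if (length(valid) == 0L) return(0)
  inv <- solve(ss$affine)
  d <- dim(mask)
  hit <- vapply(valid, function(q) {
    pts <- ss$polylines[[q]]
    ends <- pts[c(1L, nrow(pts)), , drop = FALSE]
    for (r in seq_len(nrow(ends))) {
      vox <- round((inv %*% c(ends[r, ], 1))[1:3]) + 1
      if (all(vox >= 1) && all(vox <= d) && mask[vox[1], vox[2], vox[3]])
        return(TRUE)
    }
    FALSE
  }, logical(1))
  mean(hit)
}
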