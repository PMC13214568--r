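#' fODF fields on a voxel grid
#'
#' An `fodf_field` holds per-voxel orientation density values over a shared
#' [direction_set()]: a 4-D array indexed `(i, j, k, direction)`, a 4x4
#' voxel-to-world affine (0-based voxel centers), and the direction set.
#' Densities are nonnegative and finite; negative input samples (possible
#' from upstream spherical-deconvolution output) are floored to zero at
#' construction and the count is recorded in the load report.
#'
#' @param densities numeric 4-D array `(i, j, k, direction)`.
#' @param affine 4x4 voxel-to-world matrix (default: identity, 1 mm).
#' @param directions a [direction_set()] whose count matches `dim(densities)[4]`.
#' @return An object of class `fodf_field`: list with `densities`, `affine`,
#'   `directions`, and `load_report` (`n_negative_floored`, `input_range`).
#' @export
fodf_field <- function(densities, affine = diag(4), directions = default_sphere()) {
  if (length(dim(densities)) != 4L)
    stop("fodf_field: 'densities' must be a 4-D array (i, j, k, direction)")
  if (!all(is.finite(densities)))
    stop("fodf_field: densities must be finite")
  if (dim(densities)[4] != attr(directions, "n"))
    stop(sprintf("fodf_field: direction axis (%d) does not match direction set (%d)",
                 dim(densities)[4], attr(directions, "n")))
  affine <- as.matrix(affine)
  if (!all(dim(affine) == c(4L, 4L)))
    stop("fodf_field: 'affine' must be 4x4")
  rng <- range(densities)
  n_neg <- sum(densities < 0)
  if (n_neg > 0) densities[densities < 0] <- 0
  structure(list(densities = densities, affine = affine,
                 directions = directions,
                 load_report = list(n_negative_floored = n_neg,
                                    input_range = rng)),
            class = "fodf_field")
}

#' @export
print.fodf_field <- function(x, ...) {
  d <- dim(x$densities)
  cat(sprintf("<fodf_field> grid %dx%dx%d, %d directions\n",
              d[1], d[2], d[3], d[4]))
  cat(sprintf("  density range: [%.4g, %.4g]; %d negative input samples floored\n",
              min(x$densities), max(x$densities),
              x$load_report$n_negative_floored))
  invisible(x)
}

#' Per-voxel sampling distribution of an fODF
#'
#' Converts one voxel's orientation densities into a probability mass
#' function over the direction set: negatives are floored to zero and the
#' vector is divided by its sum.  Probabilistic tracking samples step
#' directions from this pmf.
#'
#' @param f an [fodf_field()].
#' @param voxel integer 3-vector of 1-based voxel indices.
#' @return numeric vector of per-direction probabilities summing to 1
#'   (within 1e-9).
#' @export
fodf_to_pmf <- function(f, voxel) {
  stopifnot(inherits(f, "fodf_field"))
  voxel <- as.integer(voxel)
  d <- dim(f$densities)
  if (length(voxel) != 3L || any(voxel < 1L) || any(voxel > d[1:3]))
    stop("fodf_to_pmf: voxel outside grid")
  v <- f$densities[voxel[1], voxel[2], voxel[3], ]
  v[v < 0] <- 0
  s <- sum(v)
  if (s <= 0)
    stop("fodf_to_pmf: degenerate voxel (no positive density)",
         call. = FALSE)
  v / s
}

# ---- NIfTI + TSV round-tripping ------------------------------------------

#' Write / read fODF fields as NIfTI-1 + direction TSV
#'
#' The on-disk representation is a 4-D float32 NIfTI volume
#' `(i, j, k, direction)` plus a sidecar direction TSV (columns x, y, z in
#' direction-axis order).  The NIfTI sform carries the voxel-to-world
#' affine.  `read_fodf()` floors negative samples and records the input
#' range in the load report so upstream normalization conventions can be
#' audited.
#'
#' @param f an [fodf_field()].
#' @param path output NIfTI path (`.nii` or `.nii.gz`); the direction TSV
#'   is written next to it as `<path without extension>_directions.tsv`.
#' @return `write_fodf()` returns `path` invisibly; `read_fodf()` returns
#'   an [fodf_field()].
#' @export
write_fodf <- function(f, path) {
  stopifnot(inherits(f, "fodf_field"))
  img <- RNifti::asNifti(f$densities, datatype = "float")
  img <- RNifti::`sform<-`(img, structure(f$affine, code = 2L))
  RNifti::writeNifti(img, path)
  write_direction_tsv(f$directions, .sidecar_path(path))
  invisible(path)
}

#' @rdname write_fodf
#' @export
read_fodf <- function(path) {
  img <- RNifti::readNifti(path)
  aff <- matrix(as.numeric(RNifti::xform(img)), 4L, 4L)
  ds <- read_direction_tsv(.sidecar_path(path))
  fodf_field(array(as.numeric(img), dim = dim(img)), affine = aff,
             directions = ds)
}

.sidecar_path <- function(path) {
  base <- sub("\\.nii(\\.gz)?$", "", path)
  paste0(base, "_directions.tsv")
}

#' Write / read a scalar (3-D) volume as NIfTI-1
#'
#' Used for tissue maps, masks and density volumes.  Masks are written as
#' uint8, continuous volumes as float32.
#'
#' @param vol numeric or logical 3-D array.
#' @param path output path.
#' @param affine 4x4 voxel-to-world matrix.
#' @param mask logical: write as uint8 mask?
#' @return `write_volume()`: `path`, invisibly.  `read_volume()`: a list
#'   with `data` (3-D array) and `affine`.
#' @export
write_volume <- function(vol, path, affine = diag(4), mask = FALSE) {
  storage <- if (mask) "uint8" else "float"
  img <- RNifti::asNifti(array(as.numeric(vol), dim = dim(vol)),
                         datatype = storage)
  img <- RNifti::`sform<-`(img, structure(as.matrix(affine), code = 2L))
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname write_volume
#' @export
read_volume <- function(path) {
  img <- RNifti::readNifti(path)
  list(data = array(as.numeric(img), dim = dim(img)),
       affine = matrix(as.numeric(RNifti::xform(img)), 4L, 4L))
}
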