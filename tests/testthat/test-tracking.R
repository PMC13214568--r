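# a slab phantom whose every WM voxel points along a single +-axis pair
slab_field <- function(axis = c(1, 0, 0), grid = c(10, 5, 5)) {
  dirs <- small_dirs()
  n <- attr(dirs, "n")
  V <- unclass(dirs)
  hit <- which(abs(V %*% axis) > 1 - 1e-9)
  stopifnot(length(hit) == 2L)
  dens <- array(0, dim = c(grid, n))
  gm <- wm <- csf <- array(0, dim = grid)
  gm[c(1, grid[1]), , ] <- 1
  wm[2:(grid[1] - 1), , ] <- 1
  for (d in hit) dens[2:(grid[1] - 1), , , d] <- 1
  list(f = fodf_field(dens, directions = dirs),
       tissue = tissue_maps(gm, wm, csf))
}

test_that("seeding draws the configured number of points per voxel, reproducibly", {
  mask <- array(FALSE, dim = c(4, 4, 4))
  mask[2, 2, 2] <- TRUE; mask[3, 1, 4] <- TRUE
  params <- tracking_params(rng_seed = 5)
  s1 <- seed_points(mask, params)
  s2 <- seed_points(mask, params)
  expect_equal(nrow(s1), 12L)                     # 6 per voxel, 2 voxels
  expect_identical(s1, s2)
  # a large mask still gets exactly 6 per voxel
  big <- array(TRUE, dim = c(10, 10, 10))
  sb <- seed_points(big, params)
  expect_true(all(table(attr(sb, "voxel")) == 6L))
  # each point lies inside its voxel (identity affine, centers at ijk-1)
  ijk <- arrayInd(attr(s1, "voxel"), dim(mask)) - 1L
  expect_true(all(abs(s1 - ijk) <= 0.5))
  expect_error(seed_points(array(FALSE, dim = c(2, 2, 2)), params),
               "empty")
})

test_that("a single-direction field yields straight valid streamlines spanning the slab", {
  sl <- slab_field()
  seed_mask <- array(FALSE, dim = c(10, 5, 5)); seed_mask[5, 3, 3] <- TRUE
  params <- tracking_params(mode = "deterministic", rng_seed = 2,
                            seeds_per_voxel = 4)
  seeds <- seed_points(seed_mask, params)
  ss <- propagate(sl$f, sl$tissue, seeds, params)
  expect_true(all(ss$status == "valid_gm_termination"))
  for (p in ss$polylines) {
    expect_true(all(abs(diff(p[, 2])) < 1e-9))    # no y drift
    expect_true(all(abs(diff(p[, 3])) < 1e-9))    # no z drift
    # spans the whole slab: endpoints in the GM walls at x=0 and x=9
    expect_lt(min(p[, 1]), 1.01)
    expect_gt(max(p[, 1]), 7.99)
    # consecutive spacing equals the step size
    steps <- sqrt(rowSums(diff(p)^2))
    expect_true(all(abs(steps - ss$step_size_mm) < 1e-6))
  }
})

test_that("probabilistic and deterministic modes coincide in the single-direction limit", {
  sl <- slab_field()
  seed_mask <- array(FALSE, dim = c(10, 5, 5))
  seed_mask[5, 2, 2] <- TRUE; seed_mask[6, 4, 3] <- TRUE
  pd <- tracking_params(mode = "deterministic", rng_seed = 3)
  pp <- tracking_params(mode = "probabilistic", rng_seed = 3)
  seeds <- seed_points(seed_mask, pd)
  sd_ <- propagate(sl$f, sl$tissue, seeds, pd)
  sp <- propagate(sl$f, sl$tissue, seeds, pp)
  expect_identical(sd_$polylines, sp$polylines)
  expect_identical(sd_$status, sp$status)
})

test_that("an all-CSF volume discards every streamline immediately", {
  dirs <- small_dirs()
  grid <- c(4, 4, 4)
  dens <- array(1, dim = c(grid, attr(dirs, "n")))
  f <- fodf_field(dens, directions = dirs)
  tissue <- tissue_maps(array(0, grid), array(0, grid), array(1, grid))
  params <- tracking_params(rng_seed = 1)
  mask <- array(FALSE, grid); mask[2, 2, 2] <- TRUE
  ss <- propagate(f, tissue, seed_points(mask, params), params)
  expect_true(all(ss$status == "discarded_csf"))
  expect_true(all(vapply(ss$polylines, nrow, integer(1)) <= 3L))
})

test_that("statuses partition the seeds and tracking is bit-stable", {
  ph <- generate_subject(small_phantom(), 1)
  params <- tracking_params(rng_seed = 9, seeds_per_voxel = 2)
  seeds <- seed_points(ph$masks$seed_roi, params, ph$fodf$affine)
  s1 <- propagate(ph$fodf, ph$tissue, seeds, params)
  s2 <- propagate(ph$fodf, ph$tissue, seeds, params)
  expect_identical(s1$polylines, s2$polylines)
  expect_equal(length(s1$polylines), nrow(seeds))
  expect_false(any(is.na(s1$status)))
})

test_that("retained streamlines never exceed the turning-angle limit", {
  ph <- generate_subject(small_phantom(), 2)
  params <- tracking_params(rng_seed = 4, seeds_per_voxel = 3)
  seeds <- seed_points(ph$masks$seed_roi, params, ph$fodf$affine)
  ss <- propagate(ph$fodf, ph$tissue, seeds, params)
  for (q in which(ss$status == "valid_gm_termination")) {
    p <- ss$polylines[[q]]
    if (nrow(p) < 3) next
    seg <- diff(p)
    seg <- seg / sqrt(rowSums(seg^2))
    cosang <- rowSums(seg[-nrow(seg), , drop = FALSE] *
                        seg[-1, , drop = FALSE])
    ang <- acos(pmin(1, pmax(-1, cosang))) * 180 / pi
    expect_true(all(ang <= params$max_angle_deg + 1e-6))
  }
})

test_that("termination classification is a pure function of endpoint and trace", {
  grid <- c(4, 4, 4)
  gm <- array(0, grid); gm[4, , ] <- 0.9
  wm <- array(0, grid); wm[1:3, , ] <- 1
  tissue <- tissue_maps(gm, wm, array(0, grid))
  line_to_gm <- list(points = rbind(c(1, 1, 1), c(3, 1, 1)))
  expect_equal(classify_termination(line_to_gm, tissue),
               "valid_gm_termination")
  expect_equal(classify_termination(
    list(points = rbind(c(1, 1, 1)), trace = "csf_entry"), tissue),
    "discarded_csf")
  in_wm <- list(points = rbind(c(1, 1, 1), c(2, 1, 1)),
                trace = "max_steps")
  expect_equal(classify_termination(in_wm, tissue), "discarded_length")
  # idempotent
  expect_equal(classify_termination(in_wm, tissue),
               classify_termination(in_wm, tissue))
})

test_that("TCK round trip and status table preserve the streamline set", {
  sl <- slab_field()
  seed_mask <- array(FALSE, dim = c(10, 5, 5)); seed_mask[5, 3, 3] <- TRUE
  params <- tracking_params(mode = "deterministic", rng_seed = 8)
  ss <- propagate(sl$f, sl$tissue, seed_points(seed_mask, params), params)
  tck <- withr::local_tempfile(fileext = ".tck")
  write_tck(ss, tck)
  back <- read_tck(tck)
  expect_equal(length(back), length(ss$polylines))
  for (i in seq_along(back))
    expect_equal(back[[i]], .float32_mat(ss$polylines[[i]]),
                 tolerance = 1e-7)
  tsv <- withr::local_tempfile(fileext = ".tsv")
  write_streamline_status(ss, tsv)
  tab <- utils::read.table(tsv, header = TRUE, sep = "\t")
  expect_equal(tab$status, as.character(ss$status))
})
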