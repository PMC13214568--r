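# build a streamline_set by hand from polylines and statuses
fake_set <- function(polylines, status, affine = diag(4)) {
  structure(list(polylines = polylines,
                 status = factor(status,
                                 levels = c("valid_gm_termination",
                                            "discarded_csf",
                                            "discarded_angle",
                                            "discarded_length",
                                            "discarded_degenerate")),
                 seed_point = t(vapply(polylines, function(p) p[1, ],
                                       numeric(3))),
                 step_size_mm = 0.5, affine = affine),
            class = "streamline_set")
}

straight_line <- function(x0, x1, y, z, n = 40) {
  cbind(seq(x0, x1, length.out = n), y, z)
}

test_that("single and shared streamline densities match hand enumeration", {
  grid <- c(12, 4, 4)
  one <- fake_set(list(straight_line(0.8, 9.8, 1, 1)),
                  "valid_gm_termination")
  d1 <- streamline_density(one, grid)
  hit <- which(d1$density > 0)
  # world x 0.8..9.8 crosses the 10 voxels centered at 1..10 (indices 2..11)
  expect_equal(sort(unique(arrayInd(hit, grid)[, 1])), 2:11)
  expect_true(all(d1$density[hit] == 1))

  # two streamlines crossing in exactly one voxel
  a <- straight_line(0.8, 5.2, 1, 1)       # voxels x 1..6 at (y,z)=(1,1)
  b <- cbind(5, seq(0.8, 3.2, length.out = 30), 1)  # y 1..4 at x vox 6
  two <- fake_set(list(a, b), rep("valid_gm_termination", 2))
  d2 <- streamline_density(two, grid)
  expect_equal(d2$density[6, 2, 2], 1.0)         # the shared voxel
  expect_equal(d2$density[3, 2, 2], 0.5)
  expect_equal(d2$density[6, 3, 2], 0.5)
  expect_equal(d2$n_valid_streamlines, 2L)
})

test_that("discarded streamlines never contribute and re-entry counts once", {
  grid <- c(8, 4, 4)
  keep <- straight_line(0.8, 5.2, 1, 1)
  junk <- straight_line(0.8, 6.8, 2, 2)
  mixed <- fake_set(list(keep, junk),
                    c("valid_gm_termination", "discarded_csf"))
  only <- fake_set(list(keep), "valid_gm_termination")
  expect_equal(streamline_density(mixed, grid)$density,
               streamline_density(only, grid)$density)
  # a polyline that leaves and re-enters a voxel still counts it once
  loop <- rbind(straight_line(0.8, 3.2, 1, 1),
                straight_line(3.2, 0.8, 1.4, 1),
                straight_line(0.9, 3.2, 1, 1))
  dl <- streamline_density(fake_set(list(loop), "valid_gm_termination"),
                           grid)
  expect_true(all(dl$density <= 1))
})

test_that("duplicating every streamline leaves the density unchanged", {
  grid <- c(12, 4, 4)
  lines <- list(straight_line(0.8, 9.8, 1, 1),
                straight_line(0.8, 6, 2, 2))
  one <- fake_set(lines, rep("valid_gm_termination", 2))
  two <- fake_set(c(lines, lines), rep("valid_gm_termination", 4))
  expect_equal(streamline_density(one, grid)$density,
               streamline_density(two, grid)$density)
})

test_that("segment traversal matches an exact segment-cube clipping oracle", {
  grid <- c(10, 10, 10)
  set.seed(23)
  for (rep in 1:5) {
    p <- cbind(runif(8, 0.3, 8.7), runif(8, 0.3, 8.7), runif(8, 0.3, 8.7))
    got <- sort(odfreweight:::.traversed_voxels(p, diag(4), grid))
    expect_equal(got, clip_traversal_oracle(p, grid))
  }
})

test_that("streamline_density requires a valid streamline", {
  s <- fake_set(list(straight_line(0, 5, 1, 1)), "discarded_csf")
  expect_error(streamline_density(s, c(8, 4, 4)), "no valid")
})

test_that("roi_share normalizes mean densities over targets", {
  grid <- c(6, 2, 2)
  d <- structure(list(density = array(0, grid), n_valid_streamlines = 10L,
                      affine = diag(4)), class = "density_volume")
  t1 <- array(FALSE, grid); t1[1:2, , ] <- TRUE
  t2 <- array(FALSE, grid); t2[5:6, , ] <- TRUE
  d$density[t1] <- 0.02
  d$density[t2] <- 0.06
  sh <- roi_share(d, list(low = t1, high = t2))
  expect_equal(sh$normalized_share, c(0.25, 0.75))
  expect_equal(sum(sh$normalized_share), 1, tolerance = 1e-9)
  # single target -> share 1; permutation permutes rows, not values
  expect_equal(roi_share(d, list(only = t1))$normalized_share, 1)
  sh2 <- roi_share(d, list(high = t2, low = t1))
  expect_equal(sh2$normalized_share, c(0.75, 0.25))
  expect_equal(sh2$target_label, c("high", "low"))
  # global rescaling of the density leaves shares unchanged
  d3 <- d; d3$density <- d3$density * 7
  expect_equal(roi_share(d3, list(low = t1, high = t2))$normalized_share,
               sh$normalized_share)
  # overlapping targets are a mask error
  expect_error(roi_share(d, list(t1, t1)), "overlap")
})

test_that("WM-normalized density follows the stated ratio", {
  grid <- c(6, 2, 2)
  d <- structure(list(density = array(0.01, grid),
                      n_valid_streamlines = 5L, affine = diag(4)),
                 class = "density_volume")
  wm <- array(TRUE, grid)
  roi <- array(FALSE, grid); roi[1:2, , ] <- TRUE
  expect_equal(wm_normalized_density(d, roi, wm), 1.0)
  d$density[roi] <- 0.04
  d$density[!roi] <- 0.01
  # roi mean 0.04; wm mean = (8*0.04 + 16*0.01)/24
  expect_equal(wm_normalized_density(d, roi, wm),
               0.04 / mean(c(rep(0.04, 8), rep(0.01, 16))))
  expect_error(wm_normalized_density(d, array(FALSE, grid), wm), "empty")
})

test_that("direction fractions average per-voxel channel shares", {
  grid <- c(4, 2, 1)
  v <- array(0, dim = c(grid, 3))
  v[, , , 2] <- 1                          # pure A-P everywhere
  roi <- array(TRUE, grid)
  expect_equal(as.numeric(direction_fractions(v, roi)), c(0, 1, 0))
  # half the voxels M-L, half A-P
  v2 <- array(0, dim = c(grid, 3))
  v2[1:2, , , 1] <- 1
  v2[3:4, , , 2] <- 1
  fr <- direction_fractions(v2, roi)
  expect_equal(as.numeric(fr), c(0.5, 0.5, 0))
  expect_equal(sum(fr), 1, tolerance = 1e-9)
  # an all-zero voxel is excluded with a logged count
  v3 <- v2; v3[1, 1, 1, ] <- 0
  fr3 <- direction_fractions(v3, roi)
  expect_equal(attr(fr3, "n_excluded"), 1L)
  expect_equal(sum(fr3), 1, tolerance = 1e-9)
})

test_that("bundle overlap fractions sum to one and respect counts", {
  grid <- c(6, 6, 1)
  roi <- array(FALSE, grid); roi[1:4, 1:4, 1] <- TRUE
  b1 <- array(FALSE, grid); b1[1:3, 1:4, 1] <- TRUE   # 12 voxels overlap
  b2 <- array(FALSE, grid); b2[4, 1:4, 1] <- TRUE     # 4 voxels overlap
  fr <- bundle_overlap_fractions(list(big = b1, small = b2), roi)
  expect_equal(as.numeric(fr), c(0.75, 0.25))
  # one bundle covering the roi, others disjoint
  cover <- array(TRUE, grid)
  none <- array(FALSE, grid); none[6, 6, 1] <- TRUE
  expect_equal(as.numeric(bundle_overlap_fractions(
    list(a = cover, b = none), roi)), c(1, 0))
  # overlapping bundles still normalize to 1
  fr2 <- bundle_overlap_fractions(list(x = b1, y = b1, z = b2), roi)
  expect_equal(sum(fr2), 1)
  expect_error(bundle_overlap_fractions(list(n = none), roi), "no bundle")
})
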