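square_annulus <- function(outer, hole) {
  m <- matrix(TRUE, outer, outer)
  ring <- (outer - hole) %/% 2
  m[(ring + 1):(ring + hole), (ring + 1):(ring + hole)] <- FALSE
  m
}

test_that("annulus loops: exact area, closed-form diameter, contour perimeter", {
  m <- matrix(FALSE, 24, 24)
  m[3:22, 3:22] <- square_annulus(20, 10)
  lp <- detect_loops(m, pixel_size_um = 0.5)
  expect_equal(nrow(lp), 1)
  expect_equal(lp$area_px, 100)
  expect_equal(lp$area_um2, 25)
  expect_equal(lp$equiv_diameter_px, sqrt(400 / pi), tolerance = 1e-9)
  expect_equal(lp$perimeter_px, 36)   # 10x10 boundary contour, 4 x (10 - 1)
  expect_equal(lp$centroid_y, mean(8:17))
  expect_equal(lp$centroid_x, mean(8:17))
})

test_that("a gapped ring encloses nothing; disjoint annuli are separate loops", {
  m <- matrix(FALSE, 24, 24)
  m[3:22, 3:22] <- square_annulus(20, 10)
  m[12, ] <- FALSE        # cut the ring: hole touches border via the gap
  expect_equal(nrow(detect_loops(m, 0.5)), 0)
  two <- matrix(FALSE, 30, 60)
  two[3:22, 3:22] <- square_annulus(20, 10)
  two[3:22, 33:52] <- square_annulus(20, 8)
  lp <- detect_loops(two, 1)
  expect_equal(nrow(lp), 2)
  expect_equal(sort(lp$area_px), c(64, 100))
  expect_equal(length(unique(lp$loop_id)), 2)
  # holes below min_area are dropped
  tiny <- matrix(TRUE, 7, 7); tiny[4, 4] <- FALSE
  expect_equal(nrow(detect_loops(tiny, 1, min_area_px = 4)), 0)
  expect_equal(nrow(detect_loops(matrix(FALSE, 5, 5), 1)), 0)
})

test_that("nucleus snapping: distances, strict 10 um rule, tie-break, monotonicity", {
  sk <- matrix(FALSE, 40, 40)
  sk[20, 5:35] <- TRUE
  nuc <- tibble::tibble(nucleus_id = 1:3, y = c(20, 14, 44), x = c(10, 10, 10))
  sn <- snap_nuclei(nuc, sk, pixel_size_um = 1)
  expect_equal(sn$snap_dist_um, c(0, 6, 24))
  expect_equal(sn$retained, c(TRUE, TRUE, FALSE))
  # planted 12 um away: excluded by the strict < 10 um rule
  sn12 <- snap_nuclei(tibble::tibble(nucleus_id = 1, y = 8, x = 20), sk, 1)
  expect_equal(sn12$snap_dist_um, 12)
  expect_false(sn12$retained)
  # exactly 10 um is excluded too (strict)
  sn10 <- snap_nuclei(tibble::tibble(nucleus_id = 1, y = 10, x = 20), sk, 1)
  expect_false(sn10$retained)
  # equidistant between two pixels: lexicographically smaller (row, col) wins
  sk2 <- matrix(FALSE, 10, 10)
  sk2[3, 3] <- TRUE
  sk2[7, 3] <- TRUE
  tie <- snap_nuclei(tibble::tibble(nucleus_id = 1, y = 5, x = 3), sk2, 1)
  expect_equal(c(tie$skel_y, tie$skel_x), c(3, 3))
  # retention is monotone in the snap radius
  set.seed(9)
  nucr <- tibble::tibble(nucleus_id = 1:30, y = runif(30, 1, 40), x = runif(30, 1, 40))
  kept <- vapply(c(2, 5, 10, 20), function(r) {
    sum(snap_nuclei(nucr, sk, 1, max_snap_um = r)$retained)
  }, numeric(1))
  expect_true(all(diff(kept) >= 0))
  expect_error(snap_nuclei(nuc, matrix(FALSE, 5, 5), 1), "empty skeleton")
})

test_that("segment geodesic lengths and linear densities follow the closed forms", {
  # straight horizontal path of 101 px at 0.5 um/px: 50 um
  sk <- matrix(FALSE, 20, 120)
  sk[10, 10:110] <- TRUE
  nuc <- tibble::tibble(nucleus_id = 1:2, y = c(10, 11), x = c(30, 80))
  sn <- snap_nuclei(nuc, sk, 0.5)
  seg <- segment_density(sk, sn, 0.5)
  expect_equal(nrow(seg), 1)
  expect_equal(seg$length_um, 50)
  expect_equal(seg$n_nuclei, 2)
  expect_equal(seg$density_per_100um, 4)
  # diagonal path of 11 px at 1 um/px: 10 sqrt(2) um
  skd <- matrix(FALSE, 20, 20)
  for (i in 0:10) skd[5 + i, 5 + i] <- TRUE
  segd <- segment_density(skd, snap_nuclei(nuc[0, ], skd, 1), 1)
  expect_equal(segd$length_um, 10 * sqrt(2), tolerance = 1e-9)
  expect_equal(segd$n_nuclei, 0)
  expect_equal(segd$density_per_100um, 0)
})

test_that("branch points split a skeleton into segments whose lengths add up", {
  # a plus sign: four arms meeting at a central branch cluster. Under
  # 8-connectivity the centre and the first pixel of each arm all have
  # degree > 2 and collapse into one node, so each arm segment spans its
  # branch-cluster pixel to its endpoint: 9 steps of 1 px.
  sk <- matrix(FALSE, 31, 31)
  sk[16, 6:26] <- TRUE
  sk[6:26, 16] <- TRUE
  seg <- segment_density(sk, snap_nuclei(tibble::tibble(
    nucleus_id = integer(), y = double(), x = double()
  ), sk, 1), 1)
  expect_equal(nrow(seg), 4)
  expect_equal(unname(sort(seg$length_um)), rep(9, 4))
  # total = skeleton path length minus node-incident steps at the cluster
  expect_equal(sum(seg$length_um), 36)
})

test_that("planted geometry round-trips through loops, snapping and density", {
  vg <- generate_vessel_geometry(n_loops = 4, pixel_size_um = 0.6,
                                 nuclei_per_segment = c(3, 2),
                                 segment_lengths_px = c(90, 70),
                                 nuclei_offset_um = c(0, 2, 12),
                                 rng_seed = 6)
  lp <- detect_loops(vg$mask, 0.6)
  expect_equal(nrow(lp), 4)
  expect_equal(sort(lp$area_px), sort(vg$truth$loops$area_px))
  expect_equal(lp$centroid_y[order(lp$area_px)],
               vg$truth$loops$centroid_y[order(vg$truth$loops$area_px)])
  sn <- snap_nuclei(vg$nuclei, vg$skeleton, 0.6)
  expect_equal(sn$snap_dist_um, vg$nuclei$offset_um, tolerance = 1e-9)
  expect_equal(sn$retained, vg$nuclei$offset_um < 10)
  seg <- segment_density(vg$skeleton, sn, 0.6)
  expect_equal(nrow(seg), 2)
  expect_equal(sort(seg$length_um), sort(vg$truth$segments$length_um),
               tolerance = 1e-9)
  # retained nuclei land on their planted segments
  retained <- sum(vg$nuclei$offset_um < 10)
  expect_equal(sum(seg$n_nuclei), retained)
})

test_that("permeability normalisation: identity, arithmetic, scale invariance", {
  set.seed(4)
  mask <- matrix(FALSE, 30, 30)
  mask[10:20, 10:20] <- TRUE
  pre <- array(10, dim = c(30, 30, 20))
  post <- pre
  perm <- extravascular_permeability(post, mask, pre, frame_interval = 3.44)
  expect_equal(perm$series$normalized, rep(1, 20))
  # uniform extravascular 25 against pre mean 10
  post2 <- array(25, dim = c(30, 30, 20))
  perm2 <- extravascular_permeability(post2, mask, pre, 3.44)
  expect_equal(perm2$series$normalized, rep(2.5, 20))
  # scale invariance
  perm3 <- extravascular_permeability(post2 * 7, mask, pre * 7, 3.44)
  expect_equal(perm3$series$normalized, perm2$series$normalized)
  # zero pre-dextran mean is an error
  expect_error(extravascular_permeability(post2, mask, pre * 0, 3.44), "zero")
  # report times sample the nearest frames
  expect_equal(perm2$at_times$frame[perm2$at_times$time_min == 0], 1)
})

test_that("dilation margin excludes the vessel rim from the extravascular region", {
  mask <- matrix(FALSE, 20, 20)
  mask[8:12, 8:12] <- TRUE
  pre <- array(10, dim = c(20, 20, 5))
  post <- array(10, dim = c(20, 20, 5))
  post[6:14, 6:14, ] <- 100   # bright rim around the vessel
  with_margin <- extravascular_permeability(post, mask, pre, 1, dilate_px = 2)
  without <- extravascular_permeability(post, mask, pre, 1, dilate_px = 0)
  expect_lt(with_margin$series$normalized[1], without$series$normalized[1])
})
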