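# Cell-boundary pipeline: segmentation, contours, normals, membrane
# regions, partitions, windows, edge velocity, kymographs, descriptors.

test_that("segmentation recovers a noiseless disk and keeps the largest object", {
  truth <- disk_mask(30)
  cm <- segment_cell(truth * 120)
  iou <- sum(cm$mask & truth) / sum(cm$mask | truth)
  expect_gte(iou, 0.99)

  two <- disk_mask(30, shape = c(120, 200), center = c(60, 50)) +
    disk_mask(10, shape = c(120, 200), center = c(60, 150))
  cm2 <- segment_cell(two * 100)
  expect_lt(abs(cm2$area_px - pi * 30^2), 0.05 * pi * 30^2)
  expect_lt(abs(cm2$centroid[2] - 50), 2)  # the large disk survives

  expect_error(segment_cell(matrix(0, 20, 20)), "segmentation error")
})

test_that("segmentation of a binary mask image is idempotent", {
  truth <- disk_mask(25)
  cm <- segment_cell(truth, median_radius_px = 0, smooth_radius_px = 0)
  expect_identical(cm$mask > 0, truth > 0)
})

test_that("boundary tracing gives a closed 8-adjacent counter-clockwise loop", {
  sq <- rect_mask(10, 10)
  ct <- trace_boundary(sq)
  expect_equal(nrow(ct$points), 36)  # perimeter pixels of a 10x10 square
  closed <- rbind(ct$points, ct$points[1, , drop = FALSE])
  steps <- diff(closed)
  expect_true(all(abs(steps) <= 1))
  expect_true(all(rowSums(abs(steps)) >= 1))

  disk <- disk_mask(40)
  ctd <- trace_boundary(disk)
  chain <- sum(sqrt(rowSums(diff(rbind(ctd$points,
                                       ctd$points[1, , drop = FALSE]))^2)))
  expect_lt(abs(chain - 2 * pi * 40) / (2 * pi * 40), 0.10)
})

test_that("quadratic-fit normals are perpendicular, inward, and radial on a disk", {
  # straight horizontal edge of a rectangle: normals exactly vertical
  rc <- rect_mask(20, 40)
  ct <- boundary_normals(trace_boundary(rc))
  top <- which(ct$points[, "row"] == min(ct$points[, "row"]) &
               ct$points[, "col"] > min(ct$points[, "col"]) + 3 &
               ct$points[, "col"] < max(ct$points[, "col"]) - 3)
  expect_true(all(abs(ct$normals[top, "d_col"]) < 1e-9))
  expect_true(all(ct$normals[top, "d_row"] > 0.999))  # pointing into the mask

  disk <- disk_mask(50)
  ctd <- boundary_normals(trace_boundary(disk))
  ctr <- c(mean(which(rowSums(disk) > 0)), mean(which(colSums(disk) > 0)))
  inward <- sweep(-ctd$points, 2, -ctr)  # vector towards the center
  inward <- inward / sqrt(rowSums(inward^2))
  cosang <- rowSums(inward * ctd$normals)
  ang <- acos(pmin(1, pmax(-1, cosang))) * 180 / pi
  expect_lt(max(ang), 10)
})

test_that("membrane region sits inside the mask with annulus-like area", {
  disk <- disk_mask(40)
  ct <- boundary_normals(trace_boundary(disk))
  mem <- membrane_region(ct, depth_px = 5)
  expect_true(all(disk[mem] > 0))
  expected <- nrow(ct$points) * 5
  expect_lt(abs(nrow(mem) - expected) / expected, 0.15)
  expect_equal(nrow(membrane_region(ct, depth_px = 0)),
               nrow(unique(ct$points)))
})

test_that("ratio images divide pixelwise inside the mask", {
  m <- disk_mask(20)
  num <- m * 3; den <- m * 2
  r <- ratio_image(num, den, m)
  expect_true(all(r[m > 0] == 1.5))
  expect_true(all(is.na(r[m == 0])))
  same <- ratio_image(m * 7, m * 7, m)
  expect_true(all(same[m > 0] == 1))
  expect_error(ratio_image(num, m * 0, m), "denominator")
})

test_that("wedge and radial bands partition a disk with annulus-algebra areas", {
  disk <- disk_mask(40)
  part <- partition_regions(disk, c(1, 0))
  wedge_frac <- sum(part$wedge) / sum(disk)
  expect_lt(abs(wedge_frac - 0.25), 0.02)
  w <- sum(part$wedge)
  expect_lt(abs(sum(part$leading_edge) / w - 0.19), 0.03)
  expect_lt(abs(sum(part$arc_area) / w - 0.56), 0.03)
  expect_lt(abs(sum(part$center) / w - 0.25), 0.03)
  # disjoint and exhaustive
  expect_equal(sum(part$leading_edge & part$arc_area), 0)
  expect_equal(sum(part$arc_area & part$center), 0)
  expect_equal(sum(part$leading_edge & part$center), 0)
  expect_identical(part$leading_edge | part$arc_area | part$center,
                   part$wedge)
  expect_error(partition_regions(disk, c(0, 0)), "input error")
})

test_that("region intensities recover a painted wedge contrast", {
  mv <- make_moving_mask(
    1, base_radius_px = 40, shape = c(128, 128),
    intensity_fields = list(irfp = list(value = 50),
                            gfp = list(base = 100, wedge_direction = c(1, 0),
                                       wedge_factor = 2)),
    seed = 6)
  m <- mv$masks[, , 1]
  rat <- ratio_image(mv$channels$gfp[, , 1], mv$channels$irfp[, , 1], m)
  part_in <- partition_regions(m, c(1, 0))
  part_out <- partition_regions(m, c(-1, 0))
  mi <- region_intensity(rat, part_in)
  mo <- region_intensity(rat, part_out)
  expect_lt(abs(mean(mi) / mean(mo) - 2) / 2, 0.05)
  uni <- region_intensity(ratio_image(m * 5, m * 5, m), part_in)
  expect_true(all(abs(uni - 1) < 1e-12))
})

test_that("boundary windows are contiguous, balanced and anchored", {
  disk <- disk_mask(40)
  ct <- trace_boundary(disk)
  ws <- boundary_windows(ct, 60)
  sizes <- table(ws$window_id)
  expect_equal(length(sizes), 60)
  expect_lte(max(sizes) - min(sizes), 1)
  expect_equal(ws$points[1, "row"], min(ct$points[, "row"]),
               ignore_attr = TRUE)  # anchored at the topmost pixel
  expect_true(all(window_means(ws, disk * 9) == 9))
  expect_error(boundary_windows(ct, nrow(ct$points) + 1), "input error")
})

test_that("edge velocity is signed displacement of the boundary", {
  disk <- disk_mask(30)
  ws <- boundary_windows(trace_boundary(disk), 60)
  expect_true(all(edge_velocity(disk, disk, ws) == 0))
  grown <- dilate_disk(disk, 2)
  vg <- edge_velocity(disk, grown, ws, dt = 1)
  expect_true(all(abs(vg - 2) <= 0.5))
  shrunk <- erode_disk(disk, 2)
  expect_true(all(edge_velocity(disk, shrunk, ws) < 0))
})

test_that("intensity-velocity correlation finds built-in dependence", {
  withr::with_seed(10, {
    vel <- matrix(stats::rnorm(60 * 5), 60, 5)
  })
  expect_equal(intensity_velocity_correlation(vel, 2 * vel + 1)$r, 1)
  expect_equal(intensity_velocity_correlation(vel, -vel)$r, -1)
  withr::with_seed(11, {
    shuffled <- matrix(sample(as.numeric(vel)), 60, 5)
  })
  expect_lt(abs(intensity_velocity_correlation(vel, shuffled)$r), 0.2)
  expect_error(intensity_velocity_correlation(vel, matrix(1, 60, 5)),
               "constant")
})

test_that("kymographs map a moving spot to a unit-slope streak", {
  st <- array(0, c(20, 40, 6))
  for (f in 1:6) st[10, 10 + f, f] <- 1
  path <- cbind(10, 1:40)
  ky <- kymograph(st, path)
  expect_equal(dim(ky), c(40, 6))
  hits <- apply(ky, 2, which.max)
  expect_equal(diff(hits), rep(1, 5))
  static <- kymograph(array(rep(matrix(1:800, 20, 40), 3), c(20, 40, 3)), path)
  expect_true(all(static[, 1] == static[, 2]))
  expect_error(kymograph(st, cbind(10, 39:41)), "bounds")
})

test_that("shape descriptors match analytic values on simple shapes", {
  disk <- disk_mask(40)
  sd_disk <- shape_descriptors(disk)
  expect_lt(abs(sd_disk$circularity - 1), 0.10)
  expect_lt(abs(sd_disk$aspect_ratio - 1), 0.05)

  rect <- rect_mask(20, 40)
  expect_lt(abs(shape_descriptors(rect)$aspect_ratio - 2) / 2, 0.10)

  sq <- rect_mask(30, 30)
  expect_lt(abs(shape_descriptors(sq)$circularity - pi / 4) / (pi / 4), 0.10)

  # areas in physical units scale with pixel size squared
  expect_equal(shape_descriptors(sq, pixel_size_um = 0.5)$area_um2,
               sum(sq) * 0.25)
})

test_that("geometric outputs are translation invariant", {
  d1 <- disk_mask(25, shape = c(100, 100), center = c(40, 40))
  d2 <- disk_mask(25, shape = c(100, 100), center = c(55, 60))
  s1 <- shape_descriptors(d1); s2 <- shape_descriptors(d2)
  expect_equal(s1$area_um2, s2$area_um2)
  expect_equal(s1$perimeter_um, s2$perimeter_um)
  p1 <- partition_regions(d1, c(0, 1)); p2 <- partition_regions(d2, c(0, 1))
  expect_equal(sum(p1$wedge), sum(p2$wedge), tolerance = 0.02 * sum(p1$wedge))
})

test_that("moving-mask pipeline recovers the programmed drift", {
  mv <- make_moving_mask(8, base_radius_px = 25,
                         drift_px_per_frame = c(1.5, 0.5),
                         shape = c(128, 128), seed = 9)
  cents <- t(vapply(1:8, function(f) {
    cm <- segment_cell(mv$masks[, , f] * 100)
    c(x = cm$centroid[2], y = cm$centroid[1])
  }, numeric(2)))
  expect_true(all(abs(cents[, "x"] - mv$ground_truth$realized$centers[, "x"]) < 0.5))
  expect_true(all(abs(cents[, "y"] - mv$ground_truth$realized$centers[, "y"]) < 0.5))
  traj <- data.frame(t_min = 0:7, x_um = cents[, "x"], y_um = cents[, "y"])
  d <- windowed_direction(traj, 4)
  expect_lt(max(abs(d - c(1.5, 0.5))), 0.5)
})
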