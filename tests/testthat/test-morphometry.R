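test_that("binarization recovers two-level images exactly and flags flats", {
  px <- matrix(0, 30, 30); px[10:20, 10:20] <- 255
  img <- labeled_image(px, 1)
  mask <- binarize(img)
  expect_identical(unclass(mask)[, ], px == 255)

  flat <- labeled_image(matrix(5, 10, 10), 1)
  expect_warning(m2 <- binarize(flat), class = "tg_flat_image")
  expect_false(any(m2))
  expect_true(attr(m2, "flagged"))

  sim <- generate_microglia_image(microglia_scene_params(n_cells = 4, seed = 2))
  mask3 <- binarize(sim$image)
  expect_lt(abs(sum(mask3) - sum(sim$mask)) / sum(sim$mask), 0.05)
})

test_that("a straight line skeletonizes to one branch of length n-1", {
  sk <- skeletonize(line_mask(50), px_size_um = 1)
  expect_equal(sk$n_endpoints, 2L)
  expect_equal(sk$n_junctions, 0L)
  expect_equal(sk$n_branches, 1L)
  expect_equal(sk$total_length_um, 49)
})

test_that("a Y of three arms has 3 endpoints, 1 junction, 3 branches", {
  sk <- skeletonize(y_mask(20), px_size_um = 1)
  expect_equal(sk$n_endpoints, 3L)
  expect_equal(sk$n_junctions, 1L)
  expect_equal(sk$n_branches, 3L)
})

test_that("a filled disk degenerates without junctions", {
  sk <- skeletonize(disk_mask(30), px_size_um = 1)
  expect_equal(sk$n_junctions, 0L)
  expect_lte(sk$n_endpoints, 2L)
})

test_that("tree identity endpoints = junctions + 2 holds on comb trees", {
  for (nt in c(1, 3, 7, 12)) {
    sk <- skeletonize(comb_mask(nt), px_size_um = 1)
    expect_equal(sk$n_endpoints, sk$n_junctions + 2L)
    expect_equal(sk$n_junctions, nt)
  }
})

test_that("skeleton metrics are exactly invariant under 90-degree rotation", {
  sim <- generate_microglia_image(microglia_scene_params(
    n_cells = 4, branching_prob = 0.5, seed = 13))
  rot <- t(sim$mask)[ncol(sim$mask):1, , drop = FALSE]
  a <- skeletonize(sim$mask, 1)
  b <- skeletonize(rot, 1)
  expect_identical(a$n_endpoints, b$n_endpoints)
  expect_identical(a$n_junctions, b$n_junctions)
  expect_identical(a$n_branches, b$n_branches)
  expect_equal(a$total_length_um, b$total_length_um)
})

test_that("diagonal and axial lines of equal physical length agree within 10%", {
  horiz <- skeletonize(line_mask(50), 1)
  m <- matrix(FALSE, 60, 60)
  for (i in 0:35) m[10 + i, 10 + i] <- TRUE  # 35 steps * sqrt(2) = 49.5 um
  diag_sk <- skeletonize(m, 1)
  expect_lt(abs(diag_sk$total_length_um - horiz$total_length_um) /
              horiz$total_length_um, 0.1)
})

test_that("soma diameters are recovered within one pixel", {
  expect_equal(soma_diameter(disk_mask(12), 1)$diameter_um, 12, tolerance = 1)

  # disk with an attached thin process: diameter unchanged
  m <- disk_mask(12, pad = 6); c0 <- (nrow(m) + 1) %/% 2
  plain <- soma_diameter(m, 1)$diameter_um
  m2 <- cbind(m, matrix(FALSE, nrow(m), 40))
  m2[c0, (ncol(m) - 2):(ncol(m) + 38)] <- TRUE
  expect_equal(soma_diameter(m2, 1)$diameter_um, plain, tolerance = 1)

  # two disjoint disks, both recovered
  big <- matrix(FALSE, 40, 90)
  for (y in 1:40) for (x in 1:90) {
    if ((x - 20)^2 + (y - 20)^2 <= 5^2) big[y, x] <- TRUE
    if ((x - 65)^2 + (y - 20)^2 <= 7^2) big[y, x] <- TRUE
  }
  d <- sort(soma_diameter(big, 1)$diameter_um)
  expect_equal(d, c(10, 14), tolerance = 1)

  expect_equal(nrow(soma_diameter(matrix(FALSE, 10, 10), 1)), 0)
  # a 2-px-wide process fragment is not a soma
  frag <- matrix(FALSE, 20, 40); frag[10:11, 5:35] <- TRUE
  expect_equal(nrow(soma_diameter(frag, 1)), 0)
})

test_that("field metrics compose and count cells exactly on clean renders", {
  sim <- generate_microglia_image(microglia_scene_params(
    n_cells = 5, branching_prob = 0.5, seed = 7))
  fm <- field_metrics(sim$image)
  expect_equal(fm$n_cells, 5L)
  expect_equal(fm$field_area_um2, 800 * 300)
  expect_lt(abs(fm$n_endpoints - sim$ground_truth$totals$endpoints) /
              sim$ground_truth$totals$endpoints, 0.1)
  expect_lt(abs(fm$mean_soma_diameter_um -
                  mean(sim$ground_truth$cells$soma_diameter_um)), 1)

  blank <- labeled_image(matrix(0, 50, 50), 1)
  suppressWarnings(fb <- field_metrics(blank))
  expect_equal(fb$n_cells, 0L)
  expect_equal(fb$n_endpoints, 0L)
  expect_equal(fb$area_fraction, 0)
  expect_true(fb$flagged)
})

test_that("stained-area fraction matches the drawn plaque load", {
  sim <- generate_plaque_image(n_plaques = 12, seed = 31)
  fm <- field_metrics(sim$image)
  expect_equal(fm$area_fraction, sim$ground_truth$area_fraction,
               tolerance = 0.005)
})

test_that("micrometre outputs are stable under resolution doubling", {
  a <- generate_microglia_image(microglia_scene_params(
    n_cells = 3, px_per_um = 1, seed = 19))
  b <- generate_microglia_image(microglia_scene_params(
    n_cells = 3, px_per_um = 2, seed = 19))
  fa <- field_metrics(a$image); fb <- field_metrics(b$image)
  expect_equal(fa$n_cells, fb$n_cells)
  expect_lt(abs(fa$mean_soma_diameter_um - fb$mean_soma_diameter_um), 1)
  expect_lt(abs(fa$total_length_um - fb$total_length_um) /
              fa$total_length_um, 0.05)
})
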