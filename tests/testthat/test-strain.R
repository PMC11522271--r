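test_that("centerline has 61 midpoints and tracks the medial axis of a straight band", {
  ly <- straight_band_layers(thickness = 12)
  part <- partition_frame(ly)
  cl <- build_centerline(part)
  expect_equal(nrow(cl$points), 61L)
  expect_true(all(abs(cl$points[, 2] - 6) < 1))
  expect_gt(cl$length, 0)
  expect_gt(cl$length,
            sqrt(sum((cl$points[61, ] - cl$points[1, ])^2)) - 1e-12)
})

test_that("Lagrangian strain follows (l - l0)/l0 with per-cycle zeroing", {
  sc <- compute_strain_curve(c(100, 90, 80, 95), ed_frames = 1L)
  expect_equal(sc$table$strain, c(0, -0.10, -0.20, -0.05))
  expect_equal(sc$peak, 0.20)
  expect_equal(sc$peak_signed, -0.20)

  # two cycles with different reference lengths
  sc2 <- compute_strain_curve(c(100, 80, 110, 99), ed_frames = c(1L, 3L))
  expect_equal(sc2$table$strain[3], 0)
  expect_equal(sc2$table$strain[4], -0.10)
  expect_equal(sc2$cycle_peaks, c(-0.20, -0.10))
  expect_dtw_error(compute_strain_curve(c(0, 1), 1L), "invalid_reference")
})

test_that("phantom peak strain recovers the prescribed shortening", {
  ph <- cache_get("a18", function()
    generate_phantom(small_spec(shortening = 0.18)))
  res <- cache_get("a18_res", function() dtw_strain(ph$masks))
  expect_lt(abs(100 * res$curve$peak - 18), 1.5)
  expect_lt(res$curve$peak_signed, 0)  # shortening is negative strain
  expect_true(all(res$curve$table$strain <= 1e-6))
})

test_that("regional strain yields six named segment curves that tile the centerline", {
  res <- small_result()
  reg <- res$regional
  expect_equal(colnames(reg$lengths),
               c("septal_basal", "septal_mid", "septal_apical",
                 "lateral_apical", "lateral_mid", "lateral_basal"))
  ed <- res$curve$ed_frames[1]
  expect_lt(abs(sum(reg$lengths[ed, ]) - res$curve$table$l0[ed]) /
              res$curve$table$l0[ed], 0.001)
  # uniform deformation: every segmental peak near the global peak
  expect_true(all(abs(100 * abs(reg$peaks) - 100 * res$curve$peak) < 2))
  # strain is zero at ED in every segment
  expect_true(all(abs(as.matrix(reg$curves[ed, -1])) < 1e-12))
})

test_that("cycle detection finds one ED per cycle", {
  res2 <- twocycle_result()
  expect_equal(res2$curve$ed_frames, c(1L, 17L))
  expect_true(all(res2$curve$table$strain[c(1L, 17L)] == 0))

  res1 <- small_result()
  expect_equal(res1$curve$ed_frames, 1L)

  expect_equal(detect_cycles(rep(5, 10)), 1L)
})

test_that("identical frames yield exactly zero strain everywhere", {
  res <- static_result()
  expect_true(all(res$curve$table$strain == 0))
  expect_true(all(as.matrix(res$regional$curves[, -1]) == 0))
})

test_that("strain is invariant under isotropic rescaling of the masks", {
  ph <- small_phantom()
  frames2x <- lapply(ph$masks$frames[c(1, 5, 9, 13)], function(m)
    kronecker(m, matrix(1L, 2, 2)))
  # compare against the same four frames at native resolution
  res_small <- dtw_strain(mask_sequence(ph$masks$frames[c(1, 5, 9, 13)]))
  res_big <- dtw_strain(mask_sequence(frames2x))
  expect_equal(res_big$cavity$areas / res_small$cavity$areas,
               rep(4, 4), tolerance = 0.05)
  expect_lt(max(abs(res_big$curve$table$strain - res_small$curve$table$strain)),
            0.005)
})
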