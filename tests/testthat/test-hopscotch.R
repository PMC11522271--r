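test_that("points are assigned the serial of the block containing them", {
  ly <- straight_band_layers(thickness = 12)
  parts <- list(partition_frame(ly), partition_frame(ly))
  # one probe at the interior centroid of each block, both frames
  centers <- t(vapply(parts[[1]]$blocks, colMeans, numeric(2)))
  pts <- do.call(rbind, lapply(1:2, function(f)
    data.frame(frame = f, point_id = 1:60, x = centers[, 1], y = centers[, 2])))
  ser <- assign_block_serials(pts, parts)
  expect_equal(ser$serial, rep(1:60, 2))
  expect_false(any(ser$outside))
})

test_that("a point just outside the band takes the nearest block, flagged", {
  ly <- straight_band_layers(thickness = 12)
  parts <- list(partition_frame(ly), partition_frame(ly))
  b3 <- parts[[1]]$blocks[[3]]
  probe <- c(mean(range(b3[, 1])), 13)  # 1 px beyond the epicardial edge
  pts <- data.frame(frame = 1:2, point_id = 1L,
                    x = probe[1], y = probe[2])
  ser <- assign_block_serials(pts, parts)
  expect_equal(ser$serial, c(3L, 3L))
  expect_true(all(ser$outside))
})

test_that("static masks and points give a score of exactly zero", {
  res <- static_result()
  spec0 <- small_spec(shortening = 0, n_frames = 8L)
  pts <- generate_comoving_points(spec0, n_points = 50L)
  ser <- assign_block_serials(pts, res$partitions)
  for (f in 2:8)
    expect_identical(ser$serial[ser$frame == f], ser$serial[ser$frame == 1])
  sc <- hopscotch_score(ser)
  expect_identical(sc$mean_difference, 0)
  expect_identical(sc$max_abs_difference, 0L)
})

test_that("the score matches direct arithmetic on a constructed serial table", {
  n_frames <- 6L
  ser <- expand.grid(point_id = 1:50, frame = 1:n_frames)
  ser$serial <- 10L
  # point 7 sits one block higher in frames 4..6
  bump <- ser$point_id == 7L & ser$frame >= 4L
  ser$serial[bump] <- 11L
  ser$outside <- FALSE
  sc <- hopscotch_score(ser)
  expect_equal(sc$mean_difference, sum(bump) / (50 * (n_frames - 1)))
  expect_equal(sc$mean_abs_difference, sc$mean_difference)
  expect_equal(sc$max_abs_difference, 1L)
})

test_that("co-moving points stay in their blocks on the deforming phantom", {
  res <- small_result()
  pts <- generate_comoving_points(small_spec(), n_points = 50L)
  ser <- assign_block_serials(pts, res$partitions)
  sc <- hopscotch_score(ser)
  expect_lte(abs(sc$mean_difference), 0.5)
})

test_that("the score is invariant under global translation", {
  res <- static_result()
  spec0 <- small_spec(shortening = 0, n_frames = 8L)
  pts <- generate_comoving_points(spec0, n_points = 20L)
  sc1 <- hopscotch_score(assign_block_serials(pts, res$partitions))

  shift <- function(m, dr, dc) {
    out <- matrix(0L, nrow(m), ncol(m))
    out[(1 + dr):nrow(m), (1 + dc):ncol(m)] <-
      m[1:(nrow(m) - dr), 1:(ncol(m) - dc)]
    out
  }
  masks2 <- mask_sequence(lapply(static_phantom()$masks$frames, shift, dr = 5, dc = 7))
  pts2 <- transform(pts, x = x + 7, y = y + 5)
  res2 <- dtw_strain(masks2)
  sc2 <- hopscotch_score(assign_block_serials(pts2, res2$partitions))
  expect_equal(sc2$mean_difference, sc1$mean_difference)
  expect_equal(sc1$mean_difference, 0)
})

test_that("mismatched frame counts are rejected", {
  res <- static_result()
  pts <- data.frame(frame = 1:3, point_id = 1L, x = 60, y = 60)
  expect_dtw_error(assign_block_serials(pts, res$partitions), "frame_mismatch")
})
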