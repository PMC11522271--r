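test_that("boundary tracing errors on empty masks and picks the largest component", {
  expect_dtw_error(trace_boundary(matrix(0L, 32, 32)), "no_foreground")

  m <- matrix(0L, 40, 40)
  m[10:19, 10:19] <- 1L   # 100 px component
  m[30:34, 30] <- 1L      # 5 px distractor
  tb <- trace_boundary(m)
  expect_equal(tb$pixel_count, 100)
  expect_lt(abs(shoelace_area(tb$boundary) - 100) / 100, 0.02)
  # the distractor is outside the traced boundary
  expect_true(all(tb$boundary[, 1] < 25))
})

test_that("boundary shoelace area matches the pixel count on phantom frames", {
  ph <- small_phantom()
  for (f in c(1L, 9L)) {
    tb <- trace_boundary(ph$masks$frames[[f]])
    expect_lt(abs(shoelace_area(tb$boundary) - tb$pixel_count) / tb$pixel_count,
              0.02)
  }
})

test_that("a convex blob with no open base fails key point detection", {
  m <- matrix(0L, 64, 64)
  xy <- expand.grid(x = 1:64, y = 1:64)
  m[as.matrix(xy[(xy$x - 32)^2 + (xy$y - 32)^2 <= 400, c("y", "x")])] <- 1L
  expect_dtw_error(find_annular_endpoints(m), "keypoint_failure")
})

test_that("annular endpoints and apex match phantom ground truth within 3 px", {
  ph <- small_phantom()
  for (f in c(1L, 5L, 9L)) {
    cf <- extract_contour(ph$masks$frames[[f]], frame = f)
    expect_lt(sqrt(sum((cf$septal - ph$truth$base_septal[f, ])^2)), 3)
    expect_lt(sqrt(sum((cf$lateral - ph$truth$base_lateral[f, ])^2)), 3)
    expect_lt(sqrt(sum((cf$apex - ph$truth$apex_epi[f, ])^2)), 3)
  }
})

test_that("key points track a rotated phantom within 3 px", {
  ph <- cache_get("rot30", function()
    generate_phantom(small_spec(n_frames = 8L, rotation_deg = 30)))
  for (f in c(1L, 5L)) {
    cf <- extract_contour(ph$masks$frames[[f]], frame = f)
    expect_lt(sqrt(sum((cf$septal - ph$truth$base_septal[f, ])^2)), 3)
    expect_lt(sqrt(sum((cf$lateral - ph$truth$base_lateral[f, ])^2)), 3)
    expect_lt(sqrt(sum((cf$apex - ph$truth$apex_epi[f, ])^2)), 3)
  }
})

test_that("endpoints of a symmetric phantom mirror about the long axis", {
  ph <- cache_get("sym", function()
    generate_phantom(small_spec(n_frames = 8L, thickness_septal = 9,
                                thickness_lateral = 9)))
  cf <- extract_contour(ph$masks$frames[[1]])
  cx <- (ncol(ph$masks$frames[[1]]) + 1) / 2
  expect_lt(abs((cf$septal[1] + cf$lateral[1]) / 2 - cx), 2)
  expect_lt(abs(cf$septal[2] - cf$lateral[2]), 2)
})

test_that("skeleton points lie inside the foreground band", {
  ph <- small_phantom()
  cf <- extract_contour(ph$masks$frames[[1]])
  sk <- which(cf$skeleton == 1L, arr.ind = TRUE)
  expect_true(all(cf$filled[sk] == 1L))
})

test_that("apex lies farther from the annular midpoint than the endpoints", {
  ph <- small_phantom()
  cf <- extract_contour(ph$masks$frames[[1]])
  m <- (cf$septal + cf$lateral) / 2
  d <- function(p) sqrt(sum((p - m)^2))
  expect_gt(d(cf$apex), max(d(cf$septal), d(cf$lateral)))
})

test_that("cavity area defines ED and ES with earliest-frame tie-break", {
  res <- small_result()
  expect_equal(res$cavity$ed, 1L)
  expect_lte(abs(res$cavity$es - 9L), 1L)

  res0 <- static_result()
  expect_equal(res0$cavity$ed, 1L)  # all areas tie: earliest frame wins
  expect_true(all(res0$cavity$areas > 0))
})
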