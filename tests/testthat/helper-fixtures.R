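# Shared fixtures: phantoms and pipeline results are expensive, so they are
# generated once per test run and cached by name.

.fixture_cache <- new.env(parent = emptyenv())

cache_get <- function(key, make) {
  if (is.null(.fixture_cache[[key]])) .fixture_cache[[key]] <- make()
  .fixture_cache[[key]]
}

# a compact deforming phantom used by most tests
small_spec <- function(...) {
  args <- list(image_size = c(128L, 128L), base_width = 56, long_axis = 80,
               thickness_septal = 10, thickness_lateral = 8,
               shortening = 0.2, n_frames = 16L)
  dots <- list(...)
  args[names(dots)] <- dots
  do.call(phantom_spec, args)
}

small_phantom <- function() cache_get("small", function() generate_phantom(small_spec()))
small_result <- function() cache_get("small_res", function() dtw_strain(small_phantom()$masks))

static_phantom <- function() cache_get("static", function()
  generate_phantom(small_spec(shortening = 0, n_frames = 8L)))
static_result <- function() cache_get("static_res", function()
  dtw_strain(static_phantom()$masks))

twocycle_phantom <- function() cache_get("twocycle", function()
  generate_phantom(phantom_spec(image_size = c(192L, 192L), base_width = 80,
                                long_axis = 120, thickness_septal = 13,
                                thickness_lateral = 10, shortening = 0.2,
                                n_frames = 16L, n_cycles = 2L)))
twocycle_result <- function() cache_get("twocycle_res", function()
  dtw_strain(twocycle_phantom()$masks))

# full-size phantom at the validation conditions (256 px, 32 frames)
full_spec <- function(a) phantom_spec(shortening = a)
full_result <- function(a) {
  key <- sprintf("full_%03d", round(1000 * a))
  cache_get(key, function() {
    ph <- generate_phantom(full_spec(a))
    list(phantom = ph, result = dtw_strain(ph$masks))
  })
}

# straight uniform band: analytic layer contours, no rasterization
straight_band_layers <- function(n = 193L, thickness = 12) {
  x <- seq(0, n - 1)
  structure(list(
    endo = cbind(x, 0), epi = cbind(x, thickness),
    apex_index = (n + 1L) %/% 2L, cavity_area = 1, cavity_centroid = c(0, -50),
    frame = 1L
  ), class = "layer_contours")
}

# independent DTW oracle: branch-and-bound enumeration of all monotone
# paths with steps (1,0), (0,1), (1,1); exact for the small sizes used.
brute_dtw_cost <- function(a, b) {
  d <- sqrt(outer(a[, 1], b[, 1], "-")^2 + outer(a[, 2], b[, 2], "-")^2)
  n <- nrow(d); m <- ncol(d)
  best <- Inf
  rec <- function(i, j, acc) {
    acc <- acc + d[i, j]
    if (acc > best) return(invisible())
    if (i == n && j == m) {
      best <<- min(best, acc)
      return(invisible())
    }
    if (i < n && j < m) rec(i + 1L, j + 1L, acc)
    if (i < n) rec(i + 1L, j, acc)
    if (j < m) rec(i, j + 1L, acc)
  }
  rec(1L, 1L, 0)
  best
}

expect_dtw_error <- function(expr, type) {
  expect_error(expr, class = paste0("dtwstrain_", type))
}
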