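# Small planar-geometry helpers shared across modules. All polygons and
# polylines are n x 2 matrices in (x = column, y = row) pixel coordinates,
# origin top-left, y increasing downward.

#' Absolute shoelace area of a polygon
#'
#' @param poly n x 2 matrix of vertices (open: last vertex not repeated).
#' @return Non-negative area.
#' @export
shoelace_area <- function(poly) {
  x <- poly[, 1]; y <- poly[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  abs(sum(x * yn - xn * y)) / 2
}

seg_lengths <- function(pts) {
  d <- diff(pts)
  sqrt(d[, 1]^2 + d[, 2]^2)
}

polyline_length <- function(pts) sum(seg_lengths(pts))

cum_arclength <- function(pts) c(0, cumsum(seg_lengths(pts)))

# Drop consecutive duplicate vertices (within eps) so arc-length is strictly
# increasing for interpolation.
dedup_polyline <- function(pts, eps = 1e-9) {
  if (nrow(pts) < 2L) return(pts)
  keep <- c(TRUE, seg_lengths(pts) > eps)
  pts[keep, , drop = FALSE]
}

# Resample a polyline at prescribed arc-length positions (linear/chordal).
interp_polyline <- function(pts, s) {
  pts <- dedup_polyline(pts)
  cl <- cum_arclength(pts)
  s <- pmin(pmax(s, 0), cl[length(cl)])
  cbind(
    approx(cl, pts[, 1], xout = s)$y,
    approx(cl, pts[, 2], xout = s)$y
  )
}

# Centered moving-average smoothing of an open polyline; the window shrinks
# symmetrically near the ends so the endpoints stay fixed. Used to suppress
# the half-pixel staircase of rasterized boundaries before resampling.
smooth_polyline <- function(pts, window = 7L) {
  n <- nrow(pts)
  half <- (window - 1L) %/% 2L
  if (n < 2L * half + 3L || half < 1L) return(pts)
  out <- pts
  kern <- rep(1 / window, window)
  fx <- stats::filter(pts[, 1], kern, sides = 2)
  fy <- stats::filter(pts[, 2], kern, sides = 2)
  mid <- (half + 1L):(n - half)
  out[mid, 1] <- fx[mid]
  out[mid, 2] <- fy[mid]
  for (k in seq_len(half)[-1]) {  # shrinking windows toward the ends
    ix <- (k - (k - 1L)):(k + (k - 1L))
    out[k, ] <- colMeans(pts[ix, , drop = FALSE])
    out[n - k + 1L, ] <- colMeans(pts[n - ix + 1L, , drop = FALSE])
  }
  out
}

# Nearest point on a polyline to p; returns arc-length position, the foot
# point, and the distance.
project_on_polyline <- function(pts, p) {
  a <- pts[-nrow(pts), , drop = FALSE]
  b <- pts[-1, , drop = FALSE]
  ab <- b - a
  len2 <- ab[, 1]^2 + ab[, 2]^2
  len2[len2 == 0] <- 1e-300
  t <- ((p[1] - a[, 1]) * ab[, 1] + (p[2] - a[, 2]) * ab[, 2]) / len2
  t <- pmin(pmax(t, 0), 1)
  fx <- a[, 1] + t * ab[, 1]
  fy <- a[, 2] + t * ab[, 2]
  d2 <- (fx - p[1])^2 + (fy - p[2])^2
  i <- which.min(d2)
  cl <- cum_arclength(pts)
  list(
    s = cl[i] + t[i] * sqrt(len2[i]),
    point = c(fx[i], fy[i]),
    dist = sqrt(d2[i])
  )
}

# Minimum distance from point p to the (closed) polygon outline.
dist_to_polygon <- function(poly, p) {
  ring <- rbind(poly, poly[1, ])
  project_on_polyline(ring, p)$dist
}

# Point-in-polygon (boundary-tolerant). `pts` n x 2, poly m x 2 open ring.
points_in_polygon <- function(pts, poly) {
  ring <- rbind(poly, poly[1, ])
  mgcv::in.out(ring, pts)
}

rotation_matrix <- function(deg) {
  th <- deg * pi / 180
  matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
}

unit_vec <- function(v) {
  n <- sqrt(sum(v^2))
  if (n == 0) return(v)
  v / n
}

# Natural (human) ordering of file names: numeric runs compare numerically.
natural_order <- function(x) {
  parts <- strsplit(x, "(?<=\\D)(?=\\d)|(?<=\\d)(?=\\D)", perl = TRUE)
  n <- max(lengths(parts))
  keys <- lapply(seq_len(n), function(i) {
    p <- vapply(parts, function(v) if (length(v) >= i) v[i] else "", "")
    num <- suppressWarnings(as.numeric(p))
    if (all(!is.na(num) | p == "")) {
      num[p == ""] <- -Inf
      num
    } else p
  })
  do.call(order, keys)
}
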