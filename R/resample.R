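# Split the closed boundary into endocardial / epicardial arcs and resample
# each to a fixed odd point count with the apex pinned at the middle index.

#' Split a closed boundary into endocardial and epicardial arcs
#'
#' Removes the two base end-caps — boundary points lying baseward of the
#' annular endpoints (projection onto the baseward normal beyond a small
#' tolerance, assigned to the nearer annulus) — leaving exactly two arcs.
#' The arc whose mean distance to the cavity centroid is smaller is the
#' endocardium. Both arcs are reordered to run septal -> apex -> lateral.
#'
#' @param cf A `contour_frame` from [extract_contour()].
#' @return List with `endo`, `epi` (raw ordered arcs), `caps` (removed
#'   points) and `cavity_centroid`.
#' @export
split_contour_layers <- function(cf) {
  bnd <- cf$boundary
  n <- nrow(bnd)
  nb <- cf$base_normal
  d_sep <- (bnd[, 1] - cf$septal[1])^2 + (bnd[, 2] - cf$septal[2])^2
  d_lat <- (bnd[, 1] - cf$lateral[1])^2 + (bnd[, 2] - cf$lateral[2])^2
  ref <- ifelse(d_sep < d_lat, 1L, 2L)
  anch <- rbind(cf$septal, cf$lateral)
  proj <- (bnd[, 1] - anch[ref, 1]) * nb[1] + (bnd[, 2] - anch[ref, 2]) * nb[2]
  keep <- proj <= 0.35

  if (!any(!keep))
    dtw_abort("split_failure", "no base cap found on boundary", cf$frame)
  # maximal cyclic runs of kept points
  runs <- split_cyclic_runs(keep)
  runs <- runs[lengths(runs) >= 4L]
  if (length(runs) != 2L)
    dtw_abort("split_failure",
              sprintf("cap removal yielded %d arcs (expected 2)", length(runs)),
              cf$frame)
  arcs <- lapply(runs, function(idx) bnd[idx, , drop = FALSE])

  ctr <- cavity_centroid(cf)
  mean_d <- vapply(arcs, function(a)
    mean(sqrt((a[, 1] - ctr[1])^2 + (a[, 2] - ctr[2])^2)), 0)
  # light moving-average smoothing suppresses the half-pixel staircase of
  # the rasterized boundary (endpoints are preserved)
  endo <- smooth_polyline(arcs[[which.min(mean_d)]])
  epi <- smooth_polyline(arcs[[which.max(mean_d)]])
  orient <- function(a) {
    d_first <- sum((a[1, ] - cf$septal)^2)
    d_last <- sum((a[nrow(a), ] - cf$septal)^2)
    if (d_first <= d_last) a else a[nrow(a):1, , drop = FALSE]
  }
  list(endo = orient(endo), epi = orient(epi),
       caps = bnd[!keep, , drop = FALSE], cavity_centroid = ctr)
}

# indices of maximal runs of TRUE in a cyclic logical vector
split_cyclic_runs <- function(keep) {
  n <- length(keep)
  if (all(keep)) return(list(seq_len(n)))
  # rotate so position 1 is FALSE, then ordinary rle
  off <- which(!keep)[1]
  ord <- c(off:n, seq_len(off - 1L))
  k <- keep[ord]
  r <- rle(k)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  lapply(which(r$values), function(i) ord[starts[i]:ends[i]])
}

# centroid of the cavity: pixels inside the convex hull of the boundary but
# not foreground
cavity_centroid <- function(cf) {
  bnd <- cf$boundary
  hull <- bnd[chull(bnd), , drop = FALSE]
  rs <- max(1L, floor(min(bnd[, 2]))):min(nrow(cf$filled), ceiling(max(bnd[, 2])))
  cs <- max(1L, floor(min(bnd[, 1]))):min(ncol(cf$filled), ceiling(max(bnd[, 1])))
  grid <- as.matrix(expand.grid(x = cs, y = rs))
  inside <- points_in_polygon(grid, hull)
  fg <- cf$filled[cbind(grid[, 2], grid[, 1])] == 1L
  cav <- grid[inside & !fg, , drop = FALSE]
  if (nrow(cav) == 0L)
    dtw_abort("split_failure", "empty cavity region", cf$frame)
  colMeans(cav)
}

#' Resample one arc to a fixed point count with the apex pinned
#'
#' The apex is projected to the nearest position on the arc polyline; each
#' wall sub-arc (septal and lateral side of the projection) is resampled at
#' equal arc-length steps to `(n + 1)/2` points. The walls share the apex
#' sample, so the output has exactly `n` points with the apex at index
#' `(n + 1)/2`.
#'
#' @param arc Ordered arc coordinates (septal -> lateral), >= 4 points.
#' @param apex Apex coordinate to project onto the arc.
#' @param n Output point count (odd, default 193).
#' @return n x 2 matrix of coordinates; attribute `apex_index` gives the
#'   pinned index.
#' @export
resample_layer <- function(arc, apex, n = 193L) {
  if (n %% 2L != 1L) stop("point count must be odd")
  arc <- dedup_polyline(arc)
  if (nrow(arc) < 4L || polyline_length(arc) <= 0)
    dtw_abort("degenerate_arc", "arc too short to resample")
  pr <- project_on_polyline(arc, apex)
  total <- polyline_length(arc)
  s_apex <- min(max(pr$s, 1e-6 * total), (1 - 1e-6) * total)
  half <- (n + 1L) %/% 2L
  s1 <- seq(0, s_apex, length.out = half)
  s2 <- seq(s_apex, total, length.out = half)
  out <- rbind(interp_polyline(arc, s1),
               interp_polyline(arc, s2)[-1, , drop = FALSE])
  attr(out, "apex_index") <- half
  out
}

#' Split and resample a contour frame into layer contours
#'
#' @param cf A `contour_frame`.
#' @param n Points per layer (odd, default 193).
#' @return A `layer_contours` list: `endo`, `epi` (n x 2), `apex_index`,
#'   `cavity_area` (endocardial arc closed with its base chord),
#'   `cavity_centroid`, `frame`.
#' @export
resample_contour <- function(cf, n = 193L) {
  sp <- split_contour_layers(cf)
  endo <- resample_layer(sp$endo, cf$apex, n = n)
  epi <- resample_layer(sp$epi, cf$apex, n = n)
  structure(list(
    endo = endo, epi = epi, apex_index = attr(endo, "apex_index"),
    cavity_area = shoelace_area(endo),
    cavity_centroid = sp$cavity_centroid, frame = cf$frame
  ), class = "layer_contours")
}
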