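# Per-frame landmark detection: boundary tracing, annular endpoints from the
# skeleton convex hull, apex from an ellipse fit, cavity area / ED-ES.

#' Trace the myocardial boundary of a binary mask
#'
#' Keeps the largest connected foreground component, fills holes, and traces
#' one ordered closed polygon along the 0.5-level of the binary image (pixel
#' centers count as unit-square centers, so the enclosed shoelace area
#' matches the component's pixel count closely).
#'
#' @param mask Binary matrix (any nonzero is foreground).
#' @param frame Optional frame index used in error messages.
#' @return List with `boundary` (n x 2 matrix, x = col, y = row, ordered,
#'   closed implicitly), `filled` (cleaned binary matrix) and `pixel_count`.
#' @export
trace_boundary <- function(mask, frame = NULL) {
  m <- matrix(as.integer(mask != 0), nrow(mask), ncol(mask))
  if (!any(m == 1L))
    dtw_abort("no_foreground", "mask has no foreground pixels", frame)
  lab <- EBImage::bwlabel(m)
  sizes <- tabulate(lab[lab > 0])
  comp <- matrix(as.integer(lab == which.max(sizes)), nrow(m), ncol(m))
  filled <- matrix(as.integer(EBImage::fillHull(comp) != 0), nrow(m), ncol(m))

  # pad so the 0.5-contour is closed even if the component touches the edge
  pad <- matrix(0L, nrow(m) + 2L, ncol(m) + 2L)
  pad[2:(nrow(m) + 1L), 2:(ncol(m) + 1L)] <- filled
  cl <- contourLines(x = seq_len(nrow(pad)), y = seq_len(ncol(pad)),
                     z = pad, levels = 0.5)
  if (length(cl) == 0L)
    dtw_abort("no_foreground", "no boundary contour found", frame)
  polys <- lapply(cl, function(co) cbind(x = co$y - 1, y = co$x - 1))
  areas <- vapply(polys, shoelace_area, 0)
  boundary <- dedup_polyline(polys[[which.max(areas)]])
  # drop a duplicated closing vertex if present
  if (sum((boundary[1, ] - boundary[nrow(boundary), ])^2) < 1e-12)
    boundary <- boundary[-nrow(boundary), , drop = FALSE]
  list(boundary = boundary, filled = filled, pixel_count = sum(filled))
}

#' Find the septal and lateral annular endpoints
#'
#' Skeletonizes the mask, takes the convex hull of the skeleton points, and
#' scans adjacent hull vertex pairs: the pair whose chord midpoint lies
#' outside the (filled) foreground spans the open base of the U-shaped band.
#' If several pairs qualify the longest chord wins. Each endpoint is then
#' refined to the centroid of the foreground pixels in a thin slab around
#' the annular chord, which suppresses the diagonal spurs that thinning
#' produces at blunt wall ends.
#'
#' @param filled Cleaned binary matrix (from [trace_boundary()]).
#' @param septal_side `"left"` or `"right"`: which image side the septum is
#'   displayed on (standard A4C display: left).
#' @param skeleton Optional precomputed skeleton.
#' @param frame Optional frame index for error messages.
#' @return List with `septal`, `lateral` (length-2 coordinates),
#'   `base_dir` (unit vector septal -> lateral along the annular chord),
#'   `base_normal` (unit vector pointing baseward, away from the apex),
#'   `skeleton` (0/1 matrix) and `hull_pair` (the raw hull vertices).
#' @export
find_annular_endpoints <- function(filled, septal_side = "left",
                                   skeleton = NULL, frame = NULL) {
  septal_side <- match.arg(septal_side, c("left", "right"))
  if (is.null(skeleton)) skeleton <- skeletonize(filled)
  idx <- which(skeleton == 1L, arr.ind = TRUE)
  if (nrow(idx) < 3L)
    dtw_abort("keypoint_failure", "degenerate skeleton", frame)
  skpts <- cbind(x = idx[, 2], y = idx[, 1])
  h <- chull(skpts)
  hp <- skpts[h, , drop = FALSE]
  nh <- nrow(hp)
  if (nh < 3L)
    dtw_abort("keypoint_failure", "degenerate skeleton hull", frame)
  a <- hp
  b <- hp[c(2:nh, 1L), , drop = FALSE]
  mx <- (a[, 1] + b[, 1]) / 2
  my <- (a[, 2] + b[, 2]) / 2
  rr <- pmin(pmax(round(my), 1L), nrow(filled))
  cc <- pmin(pmax(round(mx), 1L), ncol(filled))
  outside <- filled[cbind(rr, cc)] == 0L
  if (!any(outside))
    dtw_abort("keypoint_failure",
              "no hull chord with exterior midpoint (mask has no open base)", frame)
  chord <- sqrt((a[, 1] - b[, 1])^2 + (a[, 2] - b[, 2])^2)
  k <- which(outside)[which.max(chord[outside])]
  v1 <- a[k, ]; v2 <- b[k, ]

  # refine: thinning retracts the skeleton from blunt wall ends, so walk
  # each endpoint out to the true wall tip — the centroid of the baseward
  # extreme slab of the foreground pixels on that side of the band
  fg <- which(filled == 1L, arr.ind = TRUE)
  fpts <- cbind(fg[, 2], fg[, 1])
  d <- unit_vec(v2 - v1)
  nvec <- unit_vec(c(-d[2], d[1]))
  ctr <- colMeans(fpts)
  mid <- (v1 + v2) / 2
  if (sum(nvec * (ctr - mid)) > 0) nvec <- -nvec
  d1 <- (fpts[, 1] - v1[1])^2 + (fpts[, 2] - v1[2])^2
  d2 <- (fpts[, 1] - v2[1])^2 + (fpts[, 2] - v2[2])^2
  ends <- list(v1, v2)
  for (side in 1:2) {
    cl <- fpts[if (side == 1) d1 < d2 else d2 <= d1, , drop = FALSE]
    if (nrow(cl) == 0L) next
    proj <- (cl[, 1] - mid[1]) * nvec[1] + (cl[, 2] - mid[2]) * nvec[2]
    tip <- cl[proj >= max(proj) - 1.5, , drop = FALSE]
    ends[[side]] <- colMeans(tip)
  }

  left_first <- ends[[1]][1] <= ends[[2]][1]
  septal_is_first <- if (septal_side == "left") left_first else !left_first
  list(
    septal = if (septal_is_first) ends[[1]] else ends[[2]],
    lateral = if (septal_is_first) ends[[2]] else ends[[1]],
    base_dir = d, base_normal = nvec, skeleton = skeleton,
    hull_pair = rbind(v1, v2)
  )
}

# Direct least-squares ellipse fit (Halir-Flusser). Returns center and the
# unit major-axis direction; errors on degenerate input.
fit_ellipse <- function(pts, frame = NULL) {
  mu <- colMeans(pts)
  sc <- max(stats::sd(pts[, 1]), stats::sd(pts[, 2]))
  if (!is.finite(sc) || sc < 1e-9)
    dtw_abort("keypoint_failure", "degenerate ellipse fit (collinear points)", frame)
  x <- (pts[, 1] - mu[1]) / sc
  y <- (pts[, 2] - mu[2]) / sc
  D1 <- cbind(x^2, x * y, y^2)
  D2 <- cbind(x, y, 1)
  S1 <- crossprod(D1); S2 <- crossprod(D1, D2); S3 <- crossprod(D2)
  Tm <- tryCatch(-solve(S3, t(S2)), error = function(e) NULL)
  if (is.null(Tm))
    dtw_abort("keypoint_failure", "degenerate ellipse fit (collinear points)", frame)
  M <- S1 + S2 %*% Tm
  M <- rbind(M[3, ] / 2, -M[2, ], M[1, ] / 2)
  ev <- eigen(M)
  vec <- Re(ev$vectors)
  cond <- 4 * vec[1, ] * vec[3, ] - vec[2, ]^2
  ok <- which(cond > 0)
  if (length(ok) == 0L)
    dtw_abort("keypoint_failure", "no ellipse solution for contour", frame)
  a1 <- vec[, ok[1]]
  conic <- c(a1, as.vector(Tm %*% a1))  # A B C D E F, scaled coordinates
  A <- conic[1]; Bc <- conic[2]; Cc <- conic[3]; Dc <- conic[4]; Ec <- conic[5]
  ctr_sc <- solve(matrix(c(2 * A, Bc, Bc, 2 * Cc), 2, 2), -c(Dc, Ec))
  Q <- matrix(c(A, Bc / 2, Bc / 2, Cc), 2, 2)
  if (sum(diag(Q)) < 0) Q <- -Q
  eq <- eigen(Q)
  major <- unit_vec(eq$vectors[, which.min(eq$values)])
  list(center = ctr_sc * sc + mu, major = major)
}

#' Locate the LV apex on the boundary
#'
#' Fits an ellipse to the boundary points; the ellipse major axis, signed to
#' point away from the annular midpoint, defines the long (y') axis. The
#' apex is the boundary point with maximal y' coordinate.
#'
#' @param boundary n x 2 boundary polygon.
#' @param septal,lateral Annular endpoint coordinates.
#' @param frame Optional frame index for error messages.
#' @return List with `apex` (coordinate), `axis` (unit long-axis vector,
#'   apex-ward) and `ellipse_center`.
#' @export
find_apex <- function(boundary, septal, lateral, frame = NULL) {
  fit <- fit_ellipse(boundary, frame = frame)
  m <- (septal + lateral) / 2
  u <- fit$major
  if (sum(u * (fit$center - m)) < 0) u <- -u
  proj <- (boundary[, 1] - m[1]) * u[1] + (boundary[, 2] - m[2]) * u[2]
  # the boundary crown at the apex is nearly flat; averaging the points
  # within 0.75 px of the maximal projection de-quantizes the estimate
  crown <- boundary[proj >= max(proj) - 0.75, , drop = FALSE]
  list(apex = colMeans(crown), axis = u, ellipse_center = fit$center)
}

#' Extract boundary and key points for one frame
#'
#' Convenience wrapper running [trace_boundary()],
#' [find_annular_endpoints()] and [find_apex()] on a single mask.
#'
#' @inheritParams trace_boundary
#' @inheritParams find_annular_endpoints
#' @return A `contour_frame` list: `boundary`, `filled`, `pixel_count`,
#'   `septal`, `lateral`, `apex`, `axis`, `base_normal`, `skeleton`, `frame`.
#' @export
extract_contour <- function(mask, septal_side = "left", frame = NULL) {
  tb <- trace_boundary(mask, frame = frame)
  ae <- find_annular_endpoints(tb$filled, septal_side = septal_side, frame = frame)
  ap <- find_apex(tb$boundary, ae$septal, ae$lateral, frame = frame)
  structure(list(
    boundary = tb$boundary, filled = tb$filled, pixel_count = tb$pixel_count,
    septal = ae$septal, lateral = ae$lateral, apex = ap$apex, axis = ap$axis,
    base_dir = ae$base_dir, base_normal = ae$base_normal,
    skeleton = ae$skeleton, frame = frame
  ), class = "contour_frame")
}

#' Cavity-area series and ED/ES frames
#'
#' The cavity area of a frame is the shoelace area of the endocardial arc
#' closed with the chord between its two base ends. End-diastole is the
#' frame of largest cavity area, end-systole the smallest; ties break to the
#' earliest frame.
#'
#' @param layers List of `layer_contours` (one per frame, from
#'   [resample_contour()]).
#' @return List with `areas` (numeric vector), `ed` and `es` (frame indices).
#' @export
cavity_area_series <- function(layers) {
  areas <- vapply(layers, function(ly) ly$cavity_area, 0)
  if (any(areas <= 0)) dtw_abort("keypoint_failure", "non-positive cavity area")
  list(areas = areas, ed = which.max(areas), es = which.min(areas))
}
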