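# DTW pairing of endocardial and epicardial wall points, unit construction,
# and merging into serially numbered blocks under proportional area
# conservation anchored at end-diastole. DTW runs per wall (septal and
# lateral separately, ends pinned) so the apex border always exists and the
# area-share constraint applies to each wall on its own.

#' Dynamic time warping alignment of two point sequences
#'
#' Classic dynamic programming with Euclidean local cost, step set
#' \{(1,0), (0,1), (1,1)\} and both ends pinned. Ties prefer the diagonal
#' step. The cost of a path is the sum of the local distances over all path
#' nodes (including the start).
#'
#' @param a,b n x 2 and m x 2 coordinate matrices (consistent orientation).
#' @return List with `path` (p x 2 matrix of 1-based index pairs into `a`
#'   and `b`) and `cost` (accumulated distance of the optimal path).
#' @export
dtw_align <- function(a, b) {
  n <- nrow(a); m <- nrow(b)
  d <- sqrt(outer(a[, 1], b[, 1], "-")^2 + outer(a[, 2], b[, 2], "-")^2)
  D <- matrix(Inf, n, m)
  D[1, 1] <- d[1, 1]
  for (j in 2:m) D[1, j] <- D[1, j - 1] + d[1, j]
  for (i in 2:n) {
    D[i, 1] <- D[i - 1, 1] + d[i, 1]
    Dp <- D[i - 1, ]
    Dc <- D[i, ]
    for (j in 2:m) {
      Dc[j] <- d[i, j] + min(Dp[j - 1], Dp[j], Dc[j - 1])
    }
    D[i, ] <- Dc
  }
  # backtrack, preferring the diagonal on ties
  path <- matrix(0L, n + m, 2)
  i <- n; j <- m; k <- 1L
  path[k, ] <- c(i, j)
  while (i > 1L || j > 1L) {
    if (i == 1L) {
      j <- j - 1L
    } else if (j == 1L) {
      i <- i - 1L
    } else {
      best <- min(D[i - 1, j - 1], D[i - 1, j], D[i, j - 1])
      if (D[i - 1, j - 1] <= best + 1e-12) {
        i <- i - 1L; j <- j - 1L
      } else if (D[i - 1, j] <= best + 1e-12) {
        i <- i - 1L
      } else {
        j <- j - 1L
      }
    }
    k <- k + 1L
    path[k, ] <- c(i, j)
  }
  list(path = path[k:1, , drop = FALSE], cost = D[n, m])
}

#' Build triangular/rectangular units from a DTW alignment
#'
#' Consecutive path nodes (i,j) -> (i',j') span the polygon
#' `a[i], a[i'], b[j'], b[j]`: a quadrilateral when both indices advance, a
#' triangle otherwise. Zero-area units (duplicate points) are dropped.
#'
#' @param alignment Result of [dtw_align()].
#' @param a,b The aligned endocardial and epicardial wall coordinates.
#' @return List with `polys` (list of polygons), `areas`, and `nodes`
#'   (for each unit, the path-node index it starts at).
#' @export
build_units <- function(alignment, a, b) {
  path <- alignment$path
  p <- nrow(path)
  polys <- vector("list", p - 1L)
  areas <- numeric(p - 1L)
  for (k in seq_len(p - 1L)) {
    i <- path[k, 1]; ip <- path[k + 1L, 1]
    j <- path[k, 2]; jp <- path[k + 1L, 2]
    poly <- rbind(a[i, ], a[ip, ], b[jp, ], b[j, ])
    poly <- dedup_polyline(poly)
    polys[[k]] <- poly
    areas[k] <- if (nrow(poly) >= 3L) shoelace_area(poly) else 0
  }
  keep <- areas > 1e-12
  list(polys = polys[keep], areas = areas[keep],
       nodes = which(keep), n_nodes = p)
}

# Snap monotone border positions: choose unit boundaries whose cumulative
# area fraction is nearest each target, strictly increasing, leaving room
# for the remaining borders. Returns boundary unit indices (border k sits
# after unit b[k]).
snap_borders <- function(areas, targets) {
  u <- length(areas)
  nb <- length(targets)
  if (u < nb + 1L)
    dtw_abort("partition_failure",
              sprintf("only %d units for %d interior borders", u, nb))
  cfrac <- cumsum(areas) / sum(areas)
  b <- integer(nb)
  prev <- 0L
  for (k in seq_len(nb)) {
    lo <- prev + 1L
    hi <- u - (nb - k) - 1L
    cand <- lo:hi
    b[k] <- cand[which.min(abs(cfrac[cand] - targets[k]))]
    prev <- b[k]
  }
  b
}

#' Record end-diastolic block targets for one wall
#'
#' Divides the wall into `n_segments` equal-area segments of
#' `blocks_per_segment` equal-area blocks each (nominal cumulative fractions
#' k/(n_segments*blocks_per_segment)), snaps each border to the nearest DTW
#' unit boundary, and records the *achieved* cumulative area fractions.
#' These post-snap fractions are the binding targets for every other frame,
#' which makes the ED frame exactly self-consistent.
#'
#' @param units Wall units from [build_units()] at the ED frame.
#' @param n_segments Segments per wall (default 3).
#' @param blocks_per_segment Blocks per segment (default 10).
#' @return List with `fractions` (achieved interior cumulative fractions,
#'   strictly increasing) and `borders` (unit indices).
#' @export
define_block_targets <- function(units, n_segments = 3L, blocks_per_segment = 10L) {
  nb <- n_segments * blocks_per_segment
  nominal <- seq_len(nb - 1L) / nb
  b <- snap_borders(units$areas, nominal)
  cfrac <- cumsum(units$areas) / sum(units$areas)
  list(fractions = cfrac[b], borders = b)
}

#' Partition one wall of one frame into blocks at the ED area fractions
#'
#' @param units Wall units from [build_units()] for this frame.
#' @param targets ED cumulative-fraction targets (from
#'   [define_block_targets()], element `fractions`).
#' @return List with `borders` (interior unit indices), `block_units`
#'   (list of unit-index runs per block), `block_areas`, `achieved`
#'   (cumulative fractions actually reached) and `max_unit_fraction`
#'   (snapping-error bound diagnostic).
#' @export
partition_wall <- function(units, targets) {
  b <- snap_borders(units$areas, targets)
  cfrac <- cumsum(units$areas) / sum(units$areas)
  bounds <- c(0L, b, length(units$areas))
  block_units <- lapply(seq_len(length(bounds) - 1L), function(k)
    (bounds[k] + 1L):bounds[k + 1L])
  list(
    borders = b,
    block_units = block_units,
    block_areas = vapply(block_units, function(ix) sum(units$areas[ix]), 0),
    achieved = cfrac[b],
    max_unit_fraction = max(units$areas) / sum(units$areas)
  )
}
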