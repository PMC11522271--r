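# Frame-level block partition: run DTW per wall, build units, place the
# 61 transversal borders, and assemble the 60 serially numbered block
# polygons (septal annulus -> apex -> lateral annulus).

wall_split <- function(layer, apex_index) {
  list(
    septal = layer[seq_len(apex_index), , drop = FALSE],
    lateral = layer[apex_index:nrow(layer), , drop = FALSE]
  )
}

# Register one wall: DTW, units, and (optionally) partition against targets.
register_wall <- function(endo_w, epi_w) {
  al <- dtw_align(endo_w, epi_w)
  un <- build_units(al, endo_w, epi_w)
  list(alignment = al, units = un)
}

#' Partition one frame into 60 area-registered blocks
#'
#' Runs DTW per wall on the resampled layer contours, builds
#' triangular/rectangular units, and merges them into blocks whose
#' cumulative area fractions match the end-diastolic targets (or, when
#' `targets` is `NULL`, defines those targets from this frame's own
#' nominal equal-area division — used at the ED frame itself).
#'
#' @param layers A `layer_contours` object from [resample_contour()].
#' @param targets `NULL`, or the result of a previous call's `$targets`
#'   (per-wall ED cumulative fractions).
#' @param n_segments Segments per wall (default 3).
#' @param blocks_per_segment Blocks per segment (default 10).
#' @return A `block_partition` list: `blocks` (list of polygons, serials
#'   1..60 septal annulus -> apex -> lateral annulus), `block_areas`,
#'   `borders` (list of 61 endo/epi segments, each a 2 x 2 matrix with rows
#'   endo, epi), `targets` (per-wall fractions), `walls` (per-wall
#'   diagnostics: unit areas, achieved fractions, max unit fraction,
#'   alignment) and `frame`.
#' @export
partition_frame <- function(layers, targets = NULL, n_segments = 3L,
                            blocks_per_segment = 10L) {
  ai <- layers$apex_index
  ew <- wall_split(layers$endo, ai)
  pw <- wall_split(layers$epi, ai)
  walls <- list(
    septal = register_wall(ew$septal, pw$septal),
    lateral = register_wall(ew$lateral, pw$lateral)
  )
  if (is.null(targets)) {
    targets <- lapply(walls, function(w)
      define_block_targets(w$units, n_segments, blocks_per_segment)$fractions)
  }
  parts <- list(
    septal = partition_wall(walls$septal$units, targets$septal),
    lateral = partition_wall(walls$lateral$units, targets$lateral)
  )

  # global point index offset of each wall in the 193-point layers
  offs <- c(septal = 0L, lateral = ai - 1L)
  wall_borders <- function(wname) {
    w <- walls[[wname]]; p <- parts[[wname]]
    nodes <- c(1L, w$units$nodes[p$borders] + 1L, nrow(w$alignment$path))
    lapply(nodes, function(np) {
      ij <- w$alignment$path[np, ]
      rbind(endo = layers$endo[ij[1] + offs[[wname]], ],
            epi = layers$epi[ij[2] + offs[[wname]], ])
    })
  }
  wall_blocks <- function(wname) {
    w <- walls[[wname]]; p <- parts[[wname]]
    lapply(p$block_units, function(q) {
      n1 <- w$units$nodes[q[1]]
      n2 <- w$units$nodes[q[length(q)]] + 1L
      i_rng <- w$alignment$path[n1, 1]:w$alignment$path[n2, 1]
      j_rng <- w$alignment$path[n1, 2]:w$alignment$path[n2, 2]
      poly <- rbind(layers$endo[i_rng + offs[[wname]], , drop = FALSE],
                    layers$epi[rev(j_rng) + offs[[wname]], , drop = FALSE])
      dedup_polyline(poly)
    })
  }
  b_sep <- wall_borders("septal")
  b_lat <- wall_borders("lateral")
  borders <- c(b_sep, b_lat[-1L])  # apex border shared
  blocks <- c(wall_blocks("septal"), wall_blocks("lateral"))
  block_areas <- c(parts$septal$block_areas, parts$lateral$block_areas)
  structure(list(
    blocks = blocks, block_areas = block_areas, borders = borders,
    serials = seq_along(blocks), targets = targets,
    walls = list(
      septal = c(walls$septal, parts$septal),
      lateral = c(walls$lateral, parts$lateral)
    ),
    n_segments = n_segments, blocks_per_segment = blocks_per_segment,
    frame = layers$frame
  ), class = "block_partition")
}
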