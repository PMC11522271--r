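# Registration-consistency ("hopscotch") metric: externally tracked points
# are pebbles on the DTW blocks; if a point keeps its block serial number
# across frames, block registration agrees with the tracking.

#' Assign block serial numbers to tracked points
#'
#' Point-in-polygon test against the 60 block polygons, in ascending serial
#' order so a point on a shared border deterministically takes the lower
#' serial. A point inside no block is assigned the block with minimal
#' boundary distance and flagged `outside`.
#'
#' @param points Data frame with columns `frame`, `point_id`, `x`, `y`.
#' @param partitions List of `block_partition` objects, one per frame.
#' @return Data frame with columns `frame`, `point_id`, `serial`, `outside`.
#' @export
assign_block_serials <- function(points, partitions) {
  frames <- sort(unique(points$frame))
  if (length(frames) != length(partitions) ||
      !all(frames == seq_along(partitions)))
    dtw_abort("frame_mismatch",
              sprintf("point table covers %d frames, partitions %d",
                      length(frames), length(partitions)))
  out <- vector("list", length(frames))
  for (f in frames) {
    pf <- points[points$frame == f, , drop = FALSE]
    xy <- cbind(pf$x, pf$y)
    np <- nrow(xy)
    serial <- rep(NA_integer_, np)
    for (s in seq_along(partitions[[f]]$blocks)) {
      unassigned <- which(is.na(serial))
      if (length(unassigned) == 0L) break
      inside <- points_in_polygon(xy[unassigned, , drop = FALSE],
                                  partitions[[f]]$blocks[[s]])
      serial[unassigned[inside]] <- s
    }
    outside <- is.na(serial)
    for (i in which(outside)) {
      dists <- vapply(partitions[[f]]$blocks, dist_to_polygon, 0, p = xy[i, ])
      serial[i] <- which.min(dists)
    }
    out[[f]] <- data.frame(frame = f, point_id = pf$point_id,
                           serial = serial, outside = outside)
  }
  do.call(rbind, out)
}

#' Hopscotch registration-consistency score
#'
#' Uses the first frame's serials as the reference and averages the signed
#' serial difference over all points and all later frames. A score near
#' zero means the block registration keeps material points in the same
#' serially numbered block throughout the cycle.
#'
#' @param serials Data frame from [assign_block_serials()].
#' @return List with `mean_difference` (signed grand mean),
#'   `mean_abs_difference`, `max_abs_difference`, `per_frame` (data frame of
#'   per-frame signed means) and `reference` (first-frame serials).
#' @export
hopscotch_score <- function(serials) {
  frames <- sort(unique(serials$frame))
  if (length(frames) < 2L) dtw_abort("empty_input", "need at least 2 frames")
  ref <- serials[serials$frame == frames[1], ]
  ref <- ref[order(ref$point_id), ]
  later <- serials[serials$frame != frames[1], ]
  later$diff <- later$serial - ref$serial[match(later$point_id, ref$point_id)]
  per_frame <- aggregate(diff ~ frame, data = later, FUN = mean)
  list(
    mean_difference = mean(later$diff),
    mean_abs_difference = mean(abs(later$diff)),
    max_abs_difference = max(abs(later$diff)),
    per_frame = per_frame,
    reference = ref[, c("point_id", "serial")]
  )
}

#' Run the hopscotch experiment on a mask sequence and a point table
#'
#' Convenience wrapper: runs the strain pipeline on the masks (to obtain
#' per-frame block partitions) and scores the tracked points against them.
#'
#' @param masks A [mask_sequence()].
#' @param points Data frame with columns `frame`, `point_id`, `x`, `y`.
#' @param ... Passed to [dtw_strain()].
#' @return List with elements `score` (from [hopscotch_score()]),
#'   `serials`, and `result` (the full [dtw_strain()] result).
#' @export
hopscotch <- function(masks, points, ...) {
  res <- dtw_strain(masks, ...)
  serials <- assign_block_serials(points, res$partitions)
  list(score = hopscotch_score(serials), serials = serials, result = res)
}
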