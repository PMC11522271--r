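# Centerline construction and Lagrangian strain: global, per cycle, and per
# segment. Strain is stored as a signed fraction; shortening is negative.

#' Centerline through the block-border midpoints
#'
#' @param partition A `block_partition` from [partition_frame()].
#' @return List with `points` (61 x 2 midpoints, septal -> lateral) and
#'   `length` (sum of consecutive Euclidean distances, px).
#' @export
build_centerline <- function(partition) {
  pts <- t(vapply(partition$borders, function(bd) colMeans(bd), numeric(2)))
  list(points = pts, length = polyline_length(pts))
}

# map every frame to the cycle whose ED frame governs its reference length
cycle_of_frame <- function(n, ed_frames) {
  ed_frames <- sort(ed_frames)
  cyc <- findInterval(seq_len(n), ed_frames)
  cyc[cyc == 0L] <- 1L  # frames before the first ED belong to the first cycle
  cyc
}

#' Lagrangian strain curve from centerline lengths
#'
#' Within each cycle the reference length l0 is that cycle's end-diastolic
#' centerline length; strain at frame i is (l_i - l0)/l0, so strain is
#' exactly zero at every ED frame. The peak strain is the maximal absolute
#' strain (sign retained separately).
#'
#' @param lengths Per-frame centerline lengths (> 0).
#' @param ed_frames One ED frame index per cycle (see [detect_cycles()]).
#' @return A `strain_curve` list: `table` (data frame: frame, cycle, length,
#'   l0, strain, is_ed), `peak` (magnitude), `peak_signed`, `peak_frame`,
#'   and `cycle_peaks` (signed peak per cycle).
#' @export
compute_strain_curve <- function(lengths, ed_frames) {
  n <- length(lengths)
  ed_frames <- sort(unique(ed_frames))
  if (any(lengths <= 0) || any(!is.finite(lengths[ed_frames])) ||
      any(lengths[ed_frames] <= 0))
    dtw_abort("invalid_reference", "non-positive centerline length")
  cyc <- cycle_of_frame(n, ed_frames)
  l0 <- lengths[ed_frames][cyc]
  strain <- (lengths - l0) / l0
  pk <- which.max(abs(strain))
  cycle_peaks <- vapply(seq_along(ed_frames), function(c) {
    s <- strain[cyc == c]
    s[which.max(abs(s))]
  }, 0)
  structure(list(
    table = data.frame(frame = seq_len(n), cycle = cyc, length = lengths,
                       l0 = l0, strain = strain,
                       is_ed = seq_len(n) %in% ed_frames),
    peak = abs(strain[pk]), peak_signed = strain[pk], peak_frame = pk,
    ed_frames = ed_frames, cycle_peaks = cycle_peaks
  ), class = "strain_curve")
}

segment_names <- function() {
  c("septal_basal", "septal_mid", "septal_apical",
    "lateral_apical", "lateral_mid", "lateral_basal")
}

# Sub-centerline lengths of the equal-area segments of one wall. Segment
# boundaries sit at the exact ED cumulative-fraction targets: each boundary
# is interpolated between the two bracketing border midpoints by area
# fraction, so segment lengths vary smoothly instead of jumping by a whole
# DTW unit when a border snaps to a different node. The segments tile the
# wall centerline exactly.
wall_segment_lengths <- function(mids, achieved, targets, n_segments,
                                 blocks_per_segment) {
  a <- c(0, achieved, 1)
  tg <- c(0, targets, 1)
  at_fraction <- function(f) {
    k <- max(1L, min(findInterval(f, a), length(a) - 1L))
    th <- (f - a[k]) / (a[k + 1] - a[k])
    mids[k, ] + th * (mids[k + 1, ] - mids[k, ])
  }
  vapply(seq_len(n_segments), function(s) {
    f_lo <- tg[(s - 1L) * blocks_per_segment + 1L]
    f_hi <- tg[s * blocks_per_segment + 1L]
    inner <- which(a > f_lo & a < f_hi)
    poly <- rbind(at_fraction(f_lo), mids[inner, , drop = FALSE],
                  at_fraction(f_hi))
    polyline_length(poly)
  }, 0)
}

#' Regional (segmental) strain curves
#'
#' Segment s covers blocks `10(s-1)+1 .. 10s` (with default block counts).
#' Its boundaries are placed at the segment's exact end-diastolic
#' cumulative-area fractions, interpolated between the bracketing block
#' border midpoints of the centerline; its own ED sub-length is the
#' reference, with the same per-cycle re-zeroing as the global curve.
#' Segments are named by the apical four-chamber convention, ordered from
#' the septal annulus.
#'
#' @param partitions List of `block_partition` objects, one per frame.
#' @param ed_frames One ED frame index per cycle.
#' @return List with `curves` (data frame of per-frame segment strains),
#'   `lengths` (per-frame sub-lengths), `peaks` (named signed peak per
#'   segment).
#' @export
regional_strain <- function(partitions, ed_frames) {
  nseg_wall <- partitions[[1]]$n_segments
  bps <- partitions[[1]]$blocks_per_segment
  nseg <- 2L * nseg_wall
  n <- length(partitions)
  cls <- lapply(partitions, build_centerline)
  nb_wall <- nseg_wall * bps
  L <- matrix(0, n, nseg)
  for (f in seq_len(n)) {
    part <- partitions[[f]]
    pts <- cls[[f]]$points
    wall_mids <- list(septal = pts[seq_len(nb_wall + 1L), , drop = FALSE],
                      lateral = pts[(nb_wall + 1L):nrow(pts), , drop = FALSE])
    for (w in 1:2) {
      wn <- names(wall_mids)[w]
      L[f, (w - 1L) * nseg_wall + seq_len(nseg_wall)] <-
        wall_segment_lengths(wall_mids[[wn]], part$walls[[wn]]$achieved,
                             part$targets[[wn]], nseg_wall, bps)
    }
  }
  cyc <- cycle_of_frame(n, sort(unique(ed_frames)))
  eds <- sort(unique(ed_frames))
  S <- matrix(0, n, nseg)
  for (s in seq_len(nseg)) {
    l0 <- L[eds, s][cyc]
    S[, s] <- (L[, s] - l0) / l0
  }
  nm <- if (nseg == 6L) segment_names() else paste0("segment_", seq_len(nseg))
  colnames(S) <- colnames(L) <- nm
  peaks <- apply(S, 2, function(s) s[which.max(abs(s))])
  list(curves = data.frame(frame = seq_len(n), S, check.names = FALSE),
       lengths = L, peaks = peaks)
}

#' Detect end-diastolic frames (one per cardiac cycle)
#'
#' ED candidates are local maxima of the cavity-area series with prominence
#' of at least `prominence_frac` of the series range; each must be followed
#' within the series by a drop of the same magnitude (end-diastole precedes
#' systole, so a terminal rise that never falls again is the truncated start
#' of a next cycle, not an ED). Candidates closer together than one third of
#' the dominant cycle length (autocorrelation estimate) are pruned keeping
#' the larger area. A constant series returns the earliest frame.
#'
#' @param areas Per-frame cavity areas.
#' @param prominence_frac Minimum prominence as a fraction of the range.
#' @param min_sep_frac Minimum ED separation as a fraction of the dominant
#'   cycle length.
#' @return Sorted integer vector of ED frame indices.
#' @export
detect_cycles <- function(areas, prominence_frac = 0.05, min_sep_frac = 1 / 3) {
  n <- length(areas)
  if (n < 2L) dtw_abort("empty_input", "need at least 2 frames")
  rng <- max(areas) - min(areas)
  if (rng <= 1e-12 * max(abs(areas), 1)) return(1L)
  thr <- prominence_frac * rng

  left <- c(TRUE, diff(areas) >= 0)
  right <- c(diff(areas) <= 0, TRUE)
  cand <- which(left & right)
  # require a following systolic drop
  suffix_min <- rev(cummin(rev(areas)))
  cand <- cand[areas[cand] - suffix_min[cand] >= thr]
  if (length(cand) == 0L) return(which.max(areas))

  # dominant cycle length from the autocorrelation of the area series
  ac <- acf(areas, lag.max = n - 2L, plot = FALSE, demean = TRUE)$acf[-1]
  period <- if (length(ac) >= 2L) which.max(ac[-1]) + 1L else n
  min_sep <- max(2L, floor(period * min_sep_frac))

  keep <- integer(0)
  for (i in cand[order(-areas[cand], cand)]) {
    if (all(abs(i - keep) >= min_sep)) keep <- c(keep, i)
  }
  sort(keep)
}
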