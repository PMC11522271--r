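# Morphological skeletonization (Zhang-Suen thinning). No installed package
# exposes 2D binary thinning, so it is implemented here; the two-subiteration
# scheme reduces the band to an 8-connected, one-pixel-wide skeleton.

shift_mat <- function(m, dr, dc) {
  h <- nrow(m); w <- ncol(m)
  out <- matrix(0L, h, w)
  rs <- max(1, 1 + dr):min(h, h + dr)
  cs <- max(1, 1 + dc):min(w, w + dc)
  out[rs, cs] <- m[rs - dr, cs - dc]
  out
}

#' Skeletonize a binary mask (Zhang-Suen thinning)
#'
#' @param mask Binary matrix (any nonzero is foreground).
#' @return Integer 0/1 matrix of the same shape: the one-pixel-wide skeleton.
#' @export
skeletonize <- function(mask) {
  full <- matrix(as.integer(mask != 0), nrow(mask), ncol(mask))
  if (!any(full == 1L)) return(full)
  # thin on the foreground bounding box (+1 px margin) only
  rr <- range(which(rowSums(full) > 0))
  cr <- range(which(colSums(full) > 0))
  rs <- max(1L, rr[1] - 1L):min(nrow(full), rr[2] + 1L)
  cs <- max(1L, cr[1] - 1L):min(ncol(full), cr[2] + 1L)
  m <- full[rs, cs, drop = FALSE]
  repeat {
    changed <- FALSE
    for (sub in 1:2) {
      # neighbours p2..p9 clockwise from north
      p2 <- shift_mat(m, 1, 0);  p3 <- shift_mat(m, 1, -1)
      p4 <- shift_mat(m, 0, -1); p5 <- shift_mat(m, -1, -1)
      p6 <- shift_mat(m, -1, 0); p7 <- shift_mat(m, -1, 1)
      p8 <- shift_mat(m, 0, 1);  p9 <- shift_mat(m, 1, 1)
      bsum <- p2 + p3 + p4 + p5 + p6 + p7 + p8 + p9
      a <- (p2 == 0 & p3 == 1) + (p3 == 0 & p4 == 1) + (p4 == 0 & p5 == 1) +
           (p5 == 0 & p6 == 1) + (p6 == 0 & p7 == 1) + (p7 == 0 & p8 == 1) +
           (p8 == 0 & p9 == 1) + (p9 == 0 & p2 == 1)
      if (sub == 1L) {
        cond <- m == 1L & bsum >= 2L & bsum <= 6L & a == 1L &
          (p2 * p4 * p6 == 0L) & (p4 * p6 * p8 == 0L)
      } else {
        cond <- m == 1L & bsum >= 2L & bsum <= 6L & a == 1L &
          (p2 * p4 * p8 == 0L) & (p2 * p6 * p8 == 0L)
      }
      if (any(cond)) {
        m[cond] <- 0L
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  out <- matrix(0L, nrow(full), ncol(full))
  out[rs, cs] <- m
  out
}
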