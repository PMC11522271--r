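# Synthetic deforming LV phantom: a U-shaped myocardial band whose
# mid-curve is a half-ellipse, shortened longitudinally by
# lambda(tau) = 1 - a * sin^2(pi * tau / n_frames) while wall thickness
# scales by 1/lambda so the in-plane band area is conserved. Ground-truth
# strain is lambda - 1, uniform along the band.

#' Specify a deforming U-band phantom
#'
#' The phantom emulates the geometry of the LV myocardium in an apical
#' four-chamber (or long-axis) view: a smooth U-shaped band from the septal
#' mitral-annular endpoint, over the apex, to the lateral annular endpoint,
#' open at the base (image bottom). Frame 1 is end-diastole; mid-cycle is
#' end-systole with longitudinal strain exactly `-shortening`.
#'
#' @param image_size `c(height, width)` in pixels.
#' @param base_width Distance in px between the two annular wall centers at
#'   end-diastole.
#' @param long_axis Base-to-apex mid-curve length in px at end-diastole
#'   (semi-axis of the half-ellipse along the long axis).
#' @param thickness_septal,thickness_lateral Wall thickness in px at the
#'   septal and lateral annulus at end-diastole; thickness varies linearly
#'   in arc length between them.
#' @param shortening Peak longitudinal shortening fraction `a` in `[0, 0.5)`;
#'   ground-truth peak strain is `-a`.
#' @param n_frames Frames per cardiac cycle (>= 8).
#' @param n_cycles Number of cycles (>= 1).
#' @param seed Integer seed used for frame jitter (only if `jitter_px > 0`).
#' @param spacing Pixel spacing in mm/px (metadata; strain is dimensionless).
#' @param rotation_deg In-plane rotation of the whole phantom about the base
#'   midpoint (default 0: apex up, base down, septal wall left).
#' @param jitter_px Standard deviation of an optional per-frame rigid
#'   translation jitter (default 0: fully deterministic analytic phantom).
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(image_size = c(256L, 256L),
                         base_width = 110,
                         long_axis = 160,
                         thickness_septal = 16,
                         thickness_lateral = 12,
                         shortening = 0.2,
                         n_frames = 32L,
                         n_cycles = 1L,
                         seed = 0L,
                         spacing = 0.6,
                         rotation_deg = 0,
                         jitter_px = 0) {
  spec <- list(
    image_size = as.integer(image_size), base_width = base_width,
    long_axis = long_axis, thickness_septal = thickness_septal,
    thickness_lateral = thickness_lateral, shortening = shortening,
    n_frames = as.integer(n_frames), n_cycles = as.integer(n_cycles),
    seed = as.integer(seed), spacing = spacing,
    rotation_deg = rotation_deg, jitter_px = jitter_px
  )
  class(spec) <- "phantom_spec"
  validate_phantom_spec(spec)
  spec
}

validate_phantom_spec <- function(spec) {
  thick <- max(spec$thickness_septal, spec$thickness_lateral)
  if (spec$shortening < 0 || spec$shortening >= 0.5)
    stop("shortening must lie in [0, 0.5)")
  if (spec$n_frames < 8L) stop("n_frames must be >= 8")
  if (spec$n_cycles < 1L) stop("n_cycles must be >= 1")
  if (thick >= spec$long_axis / 3)
    dtw_abort("self_intersection",
              "wall thickness must be < long_axis/3 (band would self-intersect)")
  lam_min <- 1 - spec$shortening
  # walls must not touch across the cavity at peak thickening
  gap <- spec$base_width * lam_min - thick / lam_min
  if (gap < 4)
    dtw_abort("self_intersection",
              "cavity closes at end-systole: reduce thickness/shortening or widen base")
  invisible(spec)
}

# Analytic geometry of one frame: arc-length parameterized mid-curve,
# local half-thickness, base clip line. Everything is derived from the ED
# half-ellipse scaled by lambda about the base midpoint, then rotated.
phantom_geometry <- function(spec, lambda, jitter = c(0, 0)) {
  h <- spec$image_size[1]; w <- spec$image_size[2]
  rx <- spec$base_width / 2
  ry <- spec$long_axis
  cx <- (w + 1) / 2
  cy <- round((h + ry) / 2)
  B <- c(cx, cy) + jitter
  R <- rotation_matrix(spec$rotation_deg)

  # dense angular sampling, then arc-length reparameterization
  u <- seq(pi, 0, length.out = 4001L)
  base_pts <- cbind(rx * cos(u), -ry * sin(u))      # relative to B, ED scale
  pts <- t(B + lambda * (R %*% t(base_pts)))
  cl <- cum_arclength(pts)
  total <- cl[length(cl)]
  frac <- cl / total

  at_fraction <- function(f) {
    cbind(approx(frac, pts[, 1], xout = f)$y,
          approx(frac, pts[, 2], xout = f)$y)
  }
  half_thickness <- function(f) {
    th <- spec$thickness_septal + (spec$thickness_lateral - spec$thickness_septal) * f
    th / 2 / lambda
  }
  list(
    base_center = B, rot = R, lambda = lambda, length = total,
    at_fraction = at_fraction, half_thickness = half_thickness,
    base_normal = as.vector(R %*% c(0, 1)),          # baseward (down) direction
    base_septal = at_fraction(0), base_lateral = at_fraction(1),
    apex_mid = at_fraction(0.5)
  )
}

# Rasterize the band: pixel centers within local half-thickness of the
# mid-curve, clipped at the annular (base) plane. Implemented by stamping
# disks at dense curve samples (0.3 px spacing).
rasterize_band <- function(spec, geom) {
  h <- spec$image_size[1]; w <- spec$image_size[2]
  m <- matrix(FALSE, h, w)
  n_samp <- max(800L, ceiling(geom$length / 0.3))
  f <- seq(0, 1, length.out = n_samp)
  P <- geom$at_fraction(f)
  hw <- geom$half_thickness(f)
  rmax <- ceiling(max(hw)) + 1L
  off <- expand.grid(dx = -rmax:rmax, dy = -rmax:rmax)
  B <- geom$base_center; nb <- geom$base_normal
  for (i in seq_len(n_samp)) {
    c0 <- round(P[i, 1]); r0 <- round(P[i, 2])
    dxf <- off$dx + (c0 - P[i, 1])
    dyf <- off$dy + (r0 - P[i, 2])
    sel <- dxf * dxf + dyf * dyf <= hw[i]^2
    if (!any(sel)) next
    cc <- c0 + off$dx[sel]; rr <- r0 + off$dy[sel]
    # clip at the annular plane: keep pixels apex-ward of the base line
    keep <- (cc - B[1]) * nb[1] + (rr - B[2]) * nb[2] <= 0.25
    keep <- keep & rr >= 1L & rr <= h & cc >= 1L & cc <= w
    if (any(keep)) m[cbind(rr[keep], cc[keep])] <- TRUE
  }
  storage.mode(m) <- "integer"
  m
}

#' Generate a deforming phantom mask sequence with ground truth
#'
#' @param spec A [phantom_spec()].
#' @return A list of class `phantom` with elements `masks` (a
#'   [mask_sequence()]) and `truth`, a list holding per-frame ground truth:
#'   `table` (data frame with frame, phase, lambda, strain, area_px),
#'   `base_septal`, `base_lateral`, `apex_mid`, `apex_epi` (per-frame
#'   coordinate matrices) and `centerline` (list of 61-point analytic
#'   mid-curves).
#' @examples
#' ph <- generate_phantom(phantom_spec(image_size = c(128, 128),
#'   base_width = 56, long_axis = 80, thickness_septal = 10,
#'   thickness_lateral = 8, n_frames = 8))
#' range(ph$truth$table$strain)
#' @export
generate_phantom <- function(spec) {
  validate_phantom_spec(spec)
  # the band (mid-curve inflated by the thickest wall) must fit the image
  h <- spec$image_size[1]; w <- spec$image_size[2]
  lam_min <- 1 - spec$shortening
  marg <- max(spec$thickness_septal, spec$thickness_lateral) / 2 / lam_min +
    2 + spec$jitter_px * 4
  g0 <- phantom_geometry(spec, 1)
  p0 <- g0$at_fraction(seq(0, 1, length.out = 201))
  if (min(p0[, 1]) - marg < 1 || max(p0[, 1]) + marg > w ||
      min(p0[, 2]) - marg < 1 || max(p0[, 2]) + 3 > h)
    stop("phantom geometry does not fit image_size: ",
         "reduce base_width/long_axis/thickness or enlarge the image")
  n_total <- spec$n_frames * spec$n_cycles
  set.seed(spec$seed)
  jit <- if (spec$jitter_px > 0)
    matrix(stats::rnorm(2 * n_total, 0, spec$jitter_px), ncol = 2)
  else matrix(0, n_total, 2)

  frames <- vector("list", n_total)
  lambda <- strain <- area <- numeric(n_total)
  bs <- bl <- am <- ae <- matrix(NA_real_, n_total, 2)
  centerline <- vector("list", n_total)
  cl_frac <- seq(0, 1, length.out = 61L)
  for (t in seq_len(n_total)) {
    phase <- (t - 1L) %% spec$n_frames
    lam <- 1 - spec$shortening * sin(pi * phase / spec$n_frames)^2
    geom <- phantom_geometry(spec, lam, jit[t, ])
    frames[[t]] <- rasterize_band(spec, geom)
    lambda[t] <- lam
    strain[t] <- lam - 1
    area[t] <- sum(frames[[t]])
    bs[t, ] <- geom$base_septal
    bl[t, ] <- geom$base_lateral
    am[t, ] <- geom$apex_mid
    # epicardial apex: mid-curve apex pushed outward (apex-ward) by the
    # local half-thickness
    apex_dir <- -geom$base_normal
    ae[t, ] <- geom$apex_mid + apex_dir * geom$half_thickness(0.5)
    centerline[[t]] <- geom$at_fraction(cl_frac)
  }
  masks <- mask_sequence(frames, spacing = spec$spacing)
  truth <- list(
    table = data.frame(frame = seq_len(n_total),
                       phase = (seq_len(n_total) - 1L) %% spec$n_frames,
                       lambda = lambda, strain = strain, area_px = area),
    base_septal = bs, base_lateral = bl, apex_mid = am, apex_epi = ae,
    centerline = centerline
  )
  structure(list(masks = masks, truth = truth, spec = spec), class = "phantom")
}

#' Analytic co-moving tracking points on the phantom mid-curve
#'
#' Places points at fixed arc-length fractions of the mid-curve and advects
#' them with the analytic deformation, i.e. each point keeps its arc-length
#' fraction in every frame (the material behaviour of the uniform
#' shortening). Fractions default to the midpoint rule `(k - 0.5)/n`.
#'
#' @param spec A [phantom_spec()].
#' @param n_points Number of points (>= 2).
#' @param fractions Optional explicit arc-length fractions in `[0, 1]`
#'   (overrides `n_points`).
#' @param layer Only `"mid"` (mid-myocardial curve) is supported.
#' @return Data frame with columns `frame`, `point_id`, `x`, `y`, `fraction`.
#' @export
generate_comoving_points <- function(spec, n_points = 50L, fractions = NULL,
                                     layer = "mid") {
  layer <- match.arg(layer, "mid")
  if (is.null(fractions)) {
    if (n_points < 2L) stop("n_points must be >= 2")
    fractions <- (seq_len(n_points) - 0.5) / n_points
  }
  validate_phantom_spec(spec)
  n_total <- spec$n_frames * spec$n_cycles
  set.seed(spec$seed)
  jit <- if (spec$jitter_px > 0)
    matrix(stats::rnorm(2 * n_total, 0, spec$jitter_px), ncol = 2)
  else matrix(0, n_total, 2)
  out <- vector("list", n_total)
  for (t in seq_len(n_total)) {
    phase <- (t - 1L) %% spec$n_frames
    lam <- 1 - spec$shortening * sin(pi * phase / spec$n_frames)^2
    geom <- phantom_geometry(spec, lam, jit[t, ])
    p <- geom$at_fraction(fractions)
    out[[t]] <- data.frame(frame = t, point_id = seq_along(fractions),
                           x = p[, 1], y = p[, 2], fraction = fractions)
  }
  do.call(rbind, out)
}
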