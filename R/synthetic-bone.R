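#' Parameters of a synthetic long bone
#'
#' Describes a hollow elliptical diaphysis with solid, flared end caps and
#' optional tuberosity-like surface bumps. The construction has a closed-form
#' midshaft cross-section — an elliptical annulus with outer semi-axes
#' `(a_mid, b_mid)` and inner semi-axes `(a_mid - t, b_mid - t)` — which makes
#' voxel-based cross-sectional measures verifiable analytically.
#'
#' The proximal half flares slightly more than the distal half, so the
#' center of mass identifies the proximal end deterministically.
#'
#' @param L functional length in mm.
#' @param a_mid,b_mid outer semi-axes of the midshaft ellipse, mm
#'   (`a_mid >= b_mid`).
#' @param t cortical thickness, mm (`b_mid > t > 0`).
#' @param flare unitless taper coefficient for epiphyseal widening (0 = a
#'   straight tube).
#' @param bump_amplitudes numeric vector of surface-bump amplitudes in mm;
#'   bumps sit at fixed parametric sites so they perturb landmarks locally.
#' @param cap_fraction fraction of `L` at each end that is solid (no marrow
#'   cavity); 0 keeps the cavity open end to end.
#' @param axis grid axis (1, 2 or 3) that carries the proximodistal direction
#'   in the voxelized output.
#' @return An object of class `bone_spec`.
#' @export
bone_spec <- function(L, a_mid, b_mid, t, flare = 0.5,
                      bump_amplitudes = numeric(0),
                      cap_fraction = 0.15, axis = 3L) {
  if (L <= 0) stopf("L must be positive")
  if (!(a_mid >= b_mid && b_mid > t && t > 0)) {
    stopf("need a_mid >= b_mid > t > 0 (got a_mid=%g, b_mid=%g, t=%g)",
          a_mid, b_mid, t)
  }
  if (flare < 0) stopf("flare must be >= 0")
  if (cap_fraction < 0 || cap_fraction >= 0.5) stopf("cap_fraction must be in [0, 0.5)")
  if (!axis %in% 1:3) stopf("axis must be 1, 2 or 3")
  structure(
    list(L = L, a_mid = a_mid, b_mid = b_mid, t = t, flare = flare,
         bump_amplitudes = as.numeric(bump_amplitudes),
         cap_fraction = cap_fraction, axis = as.integer(axis)),
    class = "bone_spec"
  )
}

# radius of an origin-centered ellipse along direction theta
ellipse_radius <- function(a, b, theta) {
  a * b / sqrt((b * cos(theta))^2 + (a * sin(theta))^2)
}

# proximal half flares 1.3x more than the distal half (center-of-mass cue);
# u in [-1, 1] with u = -1 at the proximal end
flare_scale <- function(u, flare) {
  1 + flare * u^4 * (1 + 0.3 * (u < 0))
}

# additive radial bump field at parametric sites; returns mm
bump_field <- function(theta, z, L, amplitudes) {
  m <- length(amplitudes)
  if (m == 0L) return(0)
  out <- 0
  sig_th <- pi / 8
  sig_z <- L / 20
  for (j in seq_len(m)) {
    th_j <- 2 * pi * (j - 1) / m + pi / m
    z_j <- if (j %% 2 == 1) 0.2 * L else 0.8 * L
    dth <- atan2(sin(theta - th_j), cos(theta - th_j))
    out <- out + amplitudes[j] *
      exp(-(dth^2 / (2 * sig_th^2) + (z - z_j)^2 / (2 * sig_z^2)))
  }
  out
}

#' Voxelize a synthetic bone and place corresponding landmarks
#'
#' Builds the binary occupancy grid of a [bone_spec()] at the given spacing
#' and samples landmarks on a fixed parametric `(angle, height)` grid of the
#' outer surface. Because the grid is fixed, landmark `j` corresponds across
#' all specimens by construction. Landmarks are analytic (not snapped to
#' voxels) and share the volume's physical frame in mm.
#'
#' @param spec a [bone_spec()].
#' @param spacing isotropic voxel size in mm; must satisfy
#'   `spacing <= b_mid / 5` and `t >= 2 * spacing` so the cortex is resolved.
#' @param n_theta,n_z landmark grid dimensions (`n_theta * n_z` landmarks).
#' @return A list with elements `volume` ([voxel_volume()]), `landmarks`
#'   (matrix `k x 3`, mm, rownames are landmark ids), `spec`, and `analytic`
#'   (closed-form midshaft CSA and principal second moments for validation).
#' @export
make_synthetic_bone <- function(spec, spacing, n_theta = 10L, n_z = 6L) {
  stopifnot(inherits(spec, "bone_spec"))
  if (spacing > spec$b_mid / 5) {
    stopf("spacing %g too coarse for b_mid %g (need spacing <= b_mid/5)",
          spacing, spec$b_mid)
  }
  if (spec$t < 2 * spacing) {
    stopf("spacing %g too coarse to resolve cortical thickness %g (need t >= 2*spacing)",
          spacing, spec$t)
  }
  L <- spec$L
  h <- spacing
  bump_max <- if (length(spec$bump_amplitudes)) max(spec$bump_amplitudes, 0) else 0
  r_max <- spec$a_mid * (1 + 1.3 * spec$flare) + bump_max + 2 * h

  nxy <- 2L * ceiling(r_max / h) + 1L
  nz <- ceiling(L / h)
  # voxel centers; xy centered on the bone axis, z from 0
  xy <- (seq_len(nxy) - (nxy + 1) / 2) * h
  zc <- (seq_len(nz) - 0.5) * h

  X <- matrix(xy, nxy, nxy)
  Y <- matrix(xy, nxy, nxy, byrow = TRUE)
  R <- sqrt(X^2 + Y^2)
  TH <- atan2(Y, X)

  cap <- spec$cap_fraction * L
  occ <- array(FALSE, dim = c(nxy, nxy, nz))
  for (k in seq_len(nz)) {
    z <- zc[k]
    u <- 2 * z / L - 1
    s <- flare_scale(u, spec$flare)
    rho_out <- ellipse_radius(spec$a_mid * s, spec$b_mid * s, TH) +
      bump_field(TH, z, L, spec$bump_amplitudes)
    mask <- R <= rho_out
    if (z > cap && z < L - cap) {
      rho_in <- ellipse_radius(spec$a_mid * s - spec$t, spec$b_mid * s - spec$t, TH)
      mask <- mask & (R > rho_in)
    }
    occ[, , k] <- mask
  }

  theta_g <- 2 * pi * (seq_len(n_theta) - 1) / n_theta
  z_g <- L * seq(0.05, 0.95, length.out = n_z)
  grid <- expand.grid(theta = theta_g, z = z_g)
  u_g <- 2 * grid$z / L - 1
  s_g <- flare_scale(u_g, spec$flare)
  rho <- ellipse_radius(spec$a_mid * s_g, spec$b_mid * s_g, grid$theta) +
    bump_field(grid$theta, grid$z, L, spec$bump_amplitudes)
  lmk <- cbind(x = rho * cos(grid$theta), y = rho * sin(grid$theta), z = grid$z)
  rownames(lmk) <- sprintf("L%03d", seq_len(nrow(lmk)))

  # origin maps voxel (1,1,1) center to its physical position
  origin <- c(xy[1], xy[1], zc[1])
  if (spec$axis != 3L) {
    perm <- switch(spec$axis, `1` = c(3, 1, 2), `2` = c(1, 3, 2))
    occ <- aperm(occ, perm)
    lmk <- lmk[, perm, drop = FALSE]
    colnames(lmk) <- c("x", "y", "z")
    origin <- origin[perm]
  }

  a <- spec$a_mid; b <- spec$b_mid; t <- spec$t
  analytic <- list(
    midshaft_csa = pi * (a * b - (a - t) * (b - t)),
    midshaft_I_major = pi * (a^3 * b - (a - t)^3 * (b - t)) / 4,
    midshaft_I_minor = pi * (a * b^3 - (a - t) * (b - t)^3) / 4
  )

  list(volume = voxel_volume(occ, spacing = h, origin = origin),
       landmarks = lmk, spec = spec, analytic = analytic)
}

#' Voxelize a straight elliptical tube (validation shape)
#'
#' A straight extrusion of an elliptical annulus (solid when the inner
#' semi-axes are zero), aligned with the third grid axis. Its cross-sectional
#' area, compactness and principal second moments of area have closed forms,
#' so it is the reference object for checking the slice geometry code.
#'
#' @param L extrusion length, mm.
#' @param a,b outer semi-axes, mm.
#' @param inner_a,inner_b inner (cavity) semi-axes, mm; 0 for a solid section.
#' @param spacing isotropic voxel size, mm.
#' @return A [voxel_volume()].
#' @export
voxelize_tube <- function(L, a, b, inner_a = 0, inner_b = 0, spacing) {
  stopifnot(L > 0, a >= b, b > 0, inner_a >= 0, inner_b >= 0, spacing > 0)
  h <- spacing
  nxy_x <- 2L * ceiling((a + 2 * h) / h) + 1L
  nxy_y <- 2L * ceiling((b + 2 * h) / h) + 1L
  nz <- ceiling(L / h)
  xs <- (seq_len(nxy_x) - (nxy_x + 1) / 2) * h
  ys <- (seq_len(nxy_y) - (nxy_y + 1) / 2) * h
  X <- matrix(xs, nxy_x, nxy_y)
  Y <- matrix(ys, nxy_x, nxy_y, byrow = TRUE)
  mask <- (X / a)^2 + (Y / b)^2 <= 1
  if (inner_a > 0 && inner_b > 0) {
    mask <- mask & ((X / inner_a)^2 + (Y / inner_b)^2 > 1)
  }
  occ <- array(mask, dim = c(nxy_x, nxy_y, nz))
  voxel_volume(occ, spacing = h, origin = c(xs[1], ys[1], h / 2))
}
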