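# Shared fixtures; everything is generated in code at test time.

# small simulated comparative dataset, memoized per session
small_dataset <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- simulate_dataset(evol_params(n_tips = 24L, clade_seeds = 5L,
                                             seed = 11L))
    }
    cache
  }
})

# random landmark configurations (not bone-shaped; generic shapes)
random_landmarks <- function(n, k, seed) {
  set.seed(seed)
  coords <- array(rnorm(n * k * 3), dim = c(n, k, 3))
  landmark_sample(coords)
}

# random proper rotation
random_rotation <- function() {
  q <- qr.Q(qr(matrix(rnorm(9), 3, 3)))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

# apply random rigid + scale transform to each configuration
scramble_sample <- function(sample) {
  coords <- sample$coords
  for (i in seq_len(dim(coords)[1])) {
    coords[i, , ] <- (coords[i, , ] %*% random_rotation()) * runif(1, 0.5, 2) +
      matrix(runif(3, -5, 5), dim(coords)[2], 3, byrow = TRUE)
  }
  landmark_sample(coords, dimnames(coords)[[1]], dimnames(coords)[[2]])
}

# analytic voxelization of an elliptical tube rotated about the x axis,
# used to test orientation recovery
voxelize_rotated_tube <- function(theta, L = 60, a = 4, b = 3,
                                  inner_a = 2, inner_b = 1.5, h = 0.25) {
  Rx <- matrix(c(1, 0, 0, 0, cos(theta), -sin(theta), 0, sin(theta), cos(theta)),
               3, 3, byrow = TRUE)
  ext <- abs(Rx) %*% c(a, b, L / 2)
  gx <- seq(-ext[1] - h, ext[1] + h, by = h)
  gy <- seq(-ext[2] - h, ext[2] + h, by = h)
  gz <- seq(-ext[3] - h, ext[3] + h, by = h)
  G <- as.matrix(expand.grid(gx, gy, gz))
  P <- G %*% Rx
  inside <- (P[, 1] / a)^2 + (P[, 2] / b)^2 <= 1 & abs(P[, 3]) <= L / 2
  if (inner_a > 0) {
    inside <- inside & ((P[, 1] / inner_a)^2 + (P[, 2] / inner_b)^2 > 1)
  }
  occ <- array(inside, dim = c(length(gx), length(gy), length(gz)))
  voxel_volume(occ, spacing = h)
}
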