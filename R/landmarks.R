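#' Landmark sample container
#'
#' Corresponding 3D landmark configurations for a set of specimens, stored as
#' an `n x k x 3` array in mm.
#'
#' @param coords `n x k x 3` numeric array, or a list of `k x 3` matrices.
#' @param specimens character vector of specimen ids (unique).
#' @param landmarks optional character vector of landmark ids.
#' @return An object of class `landmark_sample`.
#' @export
landmark_sample <- function(coords, specimens = NULL, landmarks = NULL) {
  if (is.list(coords)) {
    ks <- vapply(coords, nrow, integer(1))
    if (length(unique(ks)) != 1L) stopf("all configurations must share landmark count")
    if (is.null(landmarks)) landmarks <- rownames(coords[[1]])
    if (is.null(specimens)) specimens <- names(coords)
    arr <- array(NA_real_, dim = c(length(coords), ks[1], 3))
    for (i in seq_along(coords)) arr[i, , ] <- as.matrix(coords[[i]])
    coords <- arr
  }
  stopifnot(length(dim(coords)) == 3L, dim(coords)[3] == 3L)
  n <- dim(coords)[1]; k <- dim(coords)[2]
  if (is.null(specimens)) specimens <- sprintf("spec%03d", seq_len(n))
  if (is.null(landmarks)) landmarks <- sprintf("L%03d", seq_len(k))
  if (anyDuplicated(specimens)) stopf("specimen ids must be unique")
  if (anyNA(coords)) stopf("missing coordinates are not allowed")
  dimnames(coords) <- list(as.character(specimens), as.character(landmarks),
                           c("x", "y", "z"))
  structure(list(coords = coords), class = "landmark_sample")
}

#' @export
print.landmark_sample <- function(x, ...) {
  d <- dim(x$coords)
  cat(sprintf("<landmark_sample> %d specimens x %d landmarks x 3\n", d[1], d[2]))
  invisible(x)
}

#' Read landmarks from long-format CSV
#'
#' Expects columns `specimen, landmark_id, x_mm, y_mm, z_mm` (or `x, y, z`).
#'
#' @param path CSV path.
#' @return A [landmark_sample()].
#' @export
read_landmarks <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  cols <- if (all(c("x_mm", "y_mm", "z_mm") %in% names(df))) {
    c("x_mm", "y_mm", "z_mm")
  } else c("x", "y", "z")
  if (!all(c("specimen", "landmark_id", cols) %in% names(df))) {
    stopf("landmark CSV needs columns specimen, landmark_id, x[_mm], y[_mm], z[_mm]")
  }
  specs <- unique(df$specimen)
  lmks <- unique(df$landmark_id)
  arr <- array(NA_real_, dim = c(length(specs), length(lmks), 3))
  i <- match(df$specimen, specs)
  j <- match(df$landmark_id, lmks)
  for (ax in 1:3) arr[cbind(i, j, ax)] <- df[[cols[ax]]]
  landmark_sample(arr, specimens = specs, landmarks = lmks)
}

#' Write landmarks to long-format CSV
#' @param sample a [landmark_sample()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_landmarks <- function(sample, path) {
  stopifnot(inherits(sample, "landmark_sample"))
  d <- dim(sample$coords)
  df <- data.frame(
    specimen = rep(dimnames(sample$coords)[[1]], each = d[2]),
    landmark_id = rep(dimnames(sample$coords)[[2]], times = d[1]),
    x_mm = as.vector(t(sample$coords[, , 1])),
    y_mm = as.vector(t(sample$coords[, , 2])),
    z_mm = as.vector(t(sample$coords[, , 3]))
  )
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Mirror right-side configurations to the left side
#'
#' Reflects configurations labeled `"right"` across the x = 0 plane so all
#' specimens correspond to the same side before superimposition; reflection
#' is an involution and preserves centroid size and inter-landmark distances.
#'
#' @param sample a [landmark_sample()].
#' @param sides character vector (`"left"`/`"right"`) per specimen.
#' @return A [landmark_sample()] with all specimens on the left side.
#' @export
reflect_landmarks <- function(sample, sides) {
  stopifnot(inherits(sample, "landmark_sample"))
  n <- dim(sample$coords)[1]
  if (length(sides) != n) stopf("need one side label per specimen")
  bad <- setdiff(unique(sides), c("left", "right"))
  if (length(bad)) stopf("unknown side label(s): %s", paste(bad, collapse = ", "))
  coords <- sample$coords
  for (i in which(sides == "right")) coords[i, , 1] <- -coords[i, , 1]
  landmark_sample(coords, dimnames(coords)[[1]], dimnames(coords)[[2]])
}

#' Centroid size of one configuration
#' @noRd
centroid_size <- function(conf) {
  cen <- colMeans(conf)
  sqrt(sum(sweep(conf, 2, cen)^2))
}

# optimal proper rotation mapping conf onto target (both centered)
kabsch_rotation <- function(conf, target) {
  s <- svd(crossprod(conf, target))
  d <- sign(det(s$u %*% t(s$v)))
  s$u %*% diag(c(1, 1, d)) %*% t(s$v)
}

#' Generalized Procrustes Analysis
#'
#' Iterative superimposition: each configuration is centered, scaled to unit
#' centroid size, and rotated (proper rotations only) to the running
#' consensus; the consensus is the mean of aligned configurations and
#' iteration stops when it changes by less than `tol` or after `max_iter`
#' rounds. Centroid sizes are recorded before scaling. Reflections are never
#' used; mirror sides first with [reflect_landmarks()].
#'
#' @param sample a [landmark_sample()].
#' @param tol convergence tolerance on the consensus, default 1e-10.
#' @param max_iter iteration cap, default 100.
#' @return An object of class `aligned_sample`: `coords` (aligned array),
#'   `centroid_size` (named vector, mm), `consensus` (`k x 3`), `iterations`.
#' @export
gpa <- function(sample, tol = 1e-10, max_iter = 100L) {
  stopifnot(inherits(sample, "landmark_sample"))
  d <- dim(sample$coords)
  n <- d[1]; k <- d[2]
  if (n < 2L) stopf("GPA needs at least 2 specimens")
  if (k < 3L) stopf("GPA needs at least 3 landmarks")

  cs <- numeric(n)
  confs <- vector("list", n)
  for (i in seq_len(n)) {
    conf <- sample$coords[i, , ]
    cen <- colMeans(conf)
    conf <- sweep(conf, 2, cen)
    cs[i] <- sqrt(sum(conf^2))
    if (cs[i] < 1e-12) {
      stopf("specimen '%s' has coincident landmarks (zero centroid size)",
            dimnames(sample$coords)[[1]][i])
    }
    confs[[i]] <- conf / cs[i]
  }
  names(cs) <- dimnames(sample$coords)[[1]]

  consensus <- confs[[1]]
  iter <- 0L
  repeat {
    iter <- iter + 1L
    for (i in seq_len(n)) confs[[i]] <- confs[[i]] %*% kabsch_rotation(confs[[i]], consensus)
    new_consensus <- Reduce(`+`, confs) / n
    delta <- sqrt(sum((new_consensus - consensus)^2))
    consensus <- new_consensus
    if (delta < tol || iter >= max_iter) break
  }

  # canonical pose: principal axes of the consensus with a deterministic sign
  # convention, so the aligned coordinates do not depend on input orientation
  e <- eigen(crossprod(consensus), symmetric = TRUE)
  Rcan <- e$vectors
  P <- consensus %*% Rcan
  for (j in 1:3) {
    # sign from the shape itself (third moment; landmark order as fallback),
    # never from eigenvector components, which depend on the input frame
    s <- sum(P[, j]^3)
    if (abs(s) < 1e-12 * max(abs(P[, j]), 1e-300)^3) {
      k0 <- which(abs(P[, j]) > 1e-9)
      s <- if (length(k0)) P[k0[1], j] else 1
    }
    if (s < 0) {
      Rcan[, j] <- -Rcan[, j]
      P[, j] <- -P[, j]
    }
  }
  if (det(Rcan) < 0) Rcan[, 3] <- -Rcan[, 3]
  consensus <- consensus %*% Rcan
  for (i in seq_len(n)) confs[[i]] <- confs[[i]] %*% Rcan

  coords <- array(NA_real_, dim = d, dimnames = dimnames(sample$coords))
  for (i in seq_len(n)) coords[i, , ] <- confs[[i]]
  structure(
    list(coords = coords, centroid_size = cs, consensus = consensus,
         iterations = iter),
    class = "aligned_sample"
  )
}

#' @export
print.aligned_sample <- function(x, ...) {
  d <- dim(x$coords)
  cat(sprintf("<aligned_sample> %d specimens x %d landmarks (GPA, %d iterations)\n",
              d[1], d[2], x$iterations))
  invisible(x)
}

#' Flatten aligned (or raw) configurations to an n x 3k matrix
#'
#' Column order is x1, y1, z1, x2, ... per landmark.
#' @param sample a `landmark_sample` or `aligned_sample`.
#' @return Numeric matrix with specimen rownames.
#' @export
as_shape_matrix <- function(sample) {
  coords <- sample$coords
  d <- dim(coords)
  out <- matrix(aperm(coords, c(1, 3, 2)), nrow = d[1])
  rownames(out) <- dimnames(coords)[[1]]
  colnames(out) <- as.vector(t(outer(dimnames(coords)[[2]], c("x", "y", "z"), paste, sep = ".")))
  out
}

#' Procrustes distance matrix among aligned specimens
#' @param aligned an `aligned_sample`.
#' @return A `dist` object of Euclidean distances in the aligned space.
#' @export
procrustes_dist <- function(aligned) {
  stopifnot(inherits(aligned, "aligned_sample"))
  stats::dist(as_shape_matrix(aligned))
}
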