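#' Orient a volume so its dominant principal axis is the slicing axis
#'
#' Rotates the occupancy grid so the first principal axis of the occupied
#' voxel cloud lies along the third array index, which downstream slicing
#' treats as proximodistal. The sign convention is deterministic: the
#' heavier end (center of mass below the mid-extent) gets the lower slice
#' index, i.e. is treated as proximal.
#'
#' If the dominant axis already coincides with a grid axis (within ~0.06
#' degrees) the grid is only permuted/flipped, never resampled, so
#' axis-aligned input is returned bit-identical up to axis order. Otherwise
#' the volume is resampled by inverse nearest-neighbor mapping at the same
#' spacing.
#'
#' @param volume a [voxel_volume()].
#' @return An oriented [voxel_volume()].
#' @export
orient_volume <- function(volume) {
  stopifnot(inherits(volume, "voxel_volume"))
  coords <- occupied_coords(volume)
  cen <- colMeans(coords)
  cc <- sweep(coords, 2, cen)
  ev <- eigen(crossprod(cc) / nrow(cc), symmetric = TRUE)
  if (ev$values[1] < 1.05 * ev$values[2]) {
    warnf("voxel cloud is nearly isotropic; leaving orientation unchanged")
    return(volume)
  }
  v1 <- ev$vectors[, 1]

  axis_hit <- which(abs(abs(v1) - 1) < 1e-6)
  if (length(axis_hit) == 1L) {
    occ <- volume$occupancy
    if (axis_hit != 3L) {
      perm <- seq_len(3L)
      perm[c(axis_hit, 3L)] <- perm[c(3L, axis_hit)]
      occ <- aperm(occ, perm)
    }
    out <- voxel_volume(occ, spacing = volume$spacing, origin = c(0, 0, 0))
    return(flip_to_proximal(out))
  }

  # right-handed frame with v1 as the new z
  v2 <- ev$vectors[, 2]
  v3 <- ev$vectors[, 3]
  A <- cbind(v2, v3, v1)
  if (det(A) < 0) A[, 2] <- -A[, 2]

  h <- volume$spacing
  newc <- cc %*% A
  lo <- apply(newc, 2, min) - h
  hi <- apply(newc, 2, max) + h
  nd <- pmax(1L, ceiling((hi - lo) / h) + 1L)

  # inverse mapping: for each target voxel center, look up the source voxel
  gx <- lo[1] + (seq_len(nd[1]) - 1) * h
  gy <- lo[2] + (seq_len(nd[2]) - 1) * h
  gz <- lo[3] + (seq_len(nd[3]) - 1) * h
  tgt <- as.matrix(expand.grid(x = gx, y = gy, z = gz))
  src <- tgt %*% t(A)
  src <- sweep(src, 2, cen, `+`)
  idx <- round(sweep(src, 2, volume$origin) / h) + 1
  d <- dim(volume$occupancy)
  ok <- idx[, 1] >= 1 & idx[, 1] <= d[1] &
    idx[, 2] >= 1 & idx[, 2] <= d[2] &
    idx[, 3] >= 1 & idx[, 3] <= d[3]
  occ_new <- logical(nrow(idx))
  lin <- (idx[ok, 3] - 1) * d[1] * d[2] + (idx[ok, 2] - 1) * d[1] + idx[ok, 1]
  occ_new[ok] <- volume$occupancy[lin]
  out <- voxel_volume(array(occ_new, dim = nd), spacing = h, origin = c(0, 0, 0))
  flip_to_proximal(out)
}

# reverse the slicing axis if the center of mass sits in the upper half
flip_to_proximal <- function(volume) {
  occ <- volume$occupancy
  nz <- dim(occ)[3]
  mass <- vapply(seq_len(nz), function(k) sum(occ[, , k]), numeric(1))
  occ_slices <- which(mass > 0)
  com <- sum(mass * seq_len(nz)) / sum(mass)
  mid <- (min(occ_slices) + max(occ_slices)) / 2
  if (com > mid) {
    occ <- occ[, , rev(seq_len(nz)), drop = FALSE]
    volume$occupancy <- occ
  }
  volume
}

#' Functional length of an oriented volume
#'
#' Occupied extent along the slicing axis:
#' `(last occupied slice - first occupied slice + 1) * spacing`.
#'
#' @param volume an oriented [voxel_volume()].
#' @return Length in mm.
#' @export
functional_length <- function(volume) {
  stopifnot(inherits(volume, "voxel_volume"))
  occ <- apply(volume$occupancy, 3, any)
  if (!any(occ)) stopf("empty volume")
  (max(which(occ)) - min(which(occ)) + 1) * volume$spacing
}

#' Slice-by-slice cross-sectional geometry
#'
#' For every slice along the third axis computes material area
#' (`CSA = n * h^2`), hole-filled total outline area, compactness
#' (`CSA / total_area`), material centroid, and the principal second moments
#' of area about the centroid. The per-pixel self-moment `h^4/12` is included
#' in the diagonal moments, which makes the result exact for axis-aligned
#' rectangles; tools that treat pixels as point masses omit this term.
#'
#' The second-moment tensor is `[[Ixx, -Ixy], [-Ixy, Iyy]]` with
#' `Ixx = sum((y - ybar)^2) h^2 + n h^4/12`,
#' `Iyy = sum((x - xbar)^2) h^2 + n h^4/12`,
#' `Ixy = sum((x - xbar)(y - ybar)) h^2`; `I_major`/`I_minor` are its larger
#' and smaller eigenvalues, so their ratio is always >= 1.
#'
#' @param volume an oriented [voxel_volume()].
#' @return A data.frame with one row per slice: `z_index`, `z_mm`, `csa`,
#'   `total_area`, `compactness`, `centroid_x`, `centroid_y`, `i_major`,
#'   `i_minor`, `principal_angle`, `n_voxels`, `empty` (flag for slices with
#'   no material inside the bone extent).
#' @export
slice_profile <- function(volume) {
  stopifnot(inherits(volume, "voxel_volume"))
  occ <- volume$occupancy
  h <- volume$spacing
  d <- dim(occ)
  xs <- volume$origin[1] + (seq_len(d[1]) - 1) * h
  ys <- volume$origin[2] + (seq_len(d[2]) - 1) * h
  self_moment <- h^4 / 12

  rows <- lapply(seq_len(d[3]), function(k) {
    mask <- occ[, , k]
    n <- sum(mask)
    z_mm <- volume$origin[3] + (k - 1) * h
    if (n == 0L) {
      return(data.frame(
        z_index = k, z_mm = z_mm, csa = 0, total_area = 0, compactness = NA_real_,
        centroid_x = NA_real_, centroid_y = NA_real_,
        i_major = NA_real_, i_minor = NA_real_, principal_angle = NA_real_,
        n_voxels = 0L, empty = TRUE
      ))
    }
    filled <- EBImage::fillHull(mask * 1L) > 0
    idx <- which(mask, arr.ind = TRUE)
    x <- xs[idx[, 1]]
    y <- ys[idx[, 2]]
    xb <- mean(x); yb <- mean(y)
    Ixx <- sum((y - yb)^2) * h^2 + n * self_moment
    Iyy <- sum((x - xb)^2) * h^2 + n * self_moment
    Ixy <- sum((x - xb) * (y - yb)) * h^2
    tens <- matrix(c(Ixx, -Ixy, -Ixy, Iyy), 2, 2)
    ev <- eigen(tens, symmetric = TRUE)
    ang <- atan2(ev$vectors[2, 1], ev$vectors[1, 1])
    data.frame(
      z_index = k, z_mm = z_mm, csa = n * h^2, total_area = sum(filled) * h^2,
      compactness = n / sum(filled), centroid_x = xb, centroid_y = yb,
      i_major = ev$values[1], i_minor = ev$values[2], principal_angle = ang,
      n_voxels = n, empty = FALSE
    )
  })
  do.call(rbind, rows)
}

#' Slices forming the middle fraction of the functional length
#'
#' Selects slices whose centers (measured from the proximal face of the
#' first occupied slice) fall in `[(0.5 - fraction/2) L, (0.5 + fraction/2) L]`
#' and identifies the midshaft slice as the one nearest `0.5 L`, ties broken
#' toward the proximal side.
#'
#' @param profiles output of [slice_profile()].
#' @param L functional length in mm (see [functional_length()]).
#' @param fraction fraction of the functional length to include, default 0.40.
#' @return A list with `included` (z indices), `midshaft` (z index), and the
#'   window bounds in mm.
#' @export
middle_region <- function(profiles, L, fraction = 0.40) {
  if (fraction <= 0 || fraction >= 1) stopf("fraction must be in (0, 1)")
  occ_idx <- profiles$z_index[!profiles$empty]
  if (!length(occ_idx)) stopf("no occupied slices")
  first <- min(occ_idx)
  h <- if (nrow(profiles) > 1) diff(profiles$z_mm[1:2]) else L
  z_rel <- (profiles$z_index - first + 0.5) * h
  lo <- (0.5 - fraction / 2) * L
  hi <- (0.5 + fraction / 2) * L
  inc <- profiles$z_index[z_rel >= lo & z_rel <= hi & !profiles$empty]
  if (length(inc) < 3L) stopf("fewer than 3 slices in the middle region")
  cand <- profiles$z_index[!profiles$empty]
  dist_mid <- abs(z_rel[match(cand, profiles$z_index)] - 0.5 * L)
  midshaft <- cand[order(dist_mid, cand)][1]  # tie -> proximal (smaller index)
  list(included = inc, midshaft = midshaft, window_mm = c(lo, hi))
}

#' Derived structure traits over the mid-diaphysis
#'
#' * `Cg` (global compactness): mean slice compactness over the included
#'   region — proxy for resistance to axial compression.
#' * `DE` (diaphysis elongation): functional length divided by the square
#'   root of the midshaft cross-sectional area — higher is slenderer.
#' * `CSS` (cross-sectional shape): ratio of the major to minor principal
#'   second moment of area at the midshaft — 1 is circular.
#'
#' @param profiles output of [slice_profile()].
#' @param L functional length, mm.
#' @param fraction included fraction of `L` centered on the midshaft,
#'   default 0.40.
#' @return A one-row data.frame with `cg`, `de`, `css`, `length_mm`,
#'   `midshaft_csa`, and the included slice range.
#' @export
structure_traits <- function(profiles, L, fraction = 0.40) {
  reg <- middle_region(profiles, L, fraction)
  inc <- profiles[profiles$z_index %in% reg$included, ]
  mid <- profiles[profiles$z_index == reg$midshaft, ]
  data.frame(
    cg = mean(inc$compactness),
    de = L / sqrt(mid$csa),
    css = mid$i_major / mid$i_minor,
    length_mm = L,
    midshaft_csa = mid$csa,
    first_slice = min(reg$included),
    last_slice = max(reg$included)
  )
}

#' Structure traits for a batch of volumes
#'
#' Runs orientation, slicing and trait extraction per specimen. Failures are
#' recorded as error rows, never silently dropped; output order follows the
#' manifest.
#'
#' @param volumes named list of [voxel_volume()] objects, or a character
#'   vector of file paths readable by [read_volume()].
#' @param manifest data.frame with at least a `specimen` column whose values
#'   name entries of `volumes`; extra columns (e.g. ecotype, bone) are carried
#'   through.
#' @param fraction included fraction of functional length, default 0.40.
#' @param orient reorient each volume first (default TRUE).
#' @return A data.frame with one row per manifest row: traits plus an `error`
#'   column (NA on success, message on failure).
#' @export
batch_structure <- function(volumes, manifest, fraction = 0.40, orient = TRUE) {
  stopifnot(is.data.frame(manifest), "specimen" %in% names(manifest))
  get_volume <- function(id) {
    v <- volumes[[id]]
    if (is.null(v)) stopf("no volume for specimen '%s'", id)
    if (is.character(v)) v <- read_volume(v)
    v
  }
  rows <- lapply(seq_len(nrow(manifest)), function(i) {
    id <- as.character(manifest$specimen[i])
    res <- tryCatch({
      vol <- get_volume(id)
      if (orient) vol <- suppressWarnings(orient_volume(vol))
      prof <- slice_profile(vol)
      L <- functional_length(vol)
      tr <- structure_traits(prof, L, fraction)
      cbind(manifest[i, , drop = FALSE], tr, error = NA_character_,
            row.names = NULL)
    }, error = function(e) {
      cbind(manifest[i, , drop = FALSE],
            data.frame(cg = NA_real_, de = NA_real_, css = NA_real_,
                       length_mm = NA_real_, midshaft_csa = NA_real_,
                       first_slice = NA_integer_, last_slice = NA_integer_,
                       error = conditionMessage(e)),
            row.names = NULL)
    })
    res
  })
  do.call(rbind, rows)
}
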