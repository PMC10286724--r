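test_that("functional length counts occupied slices times spacing", {
  occ <- array(FALSE, dim = c(5, 5, 120))
  occ[2:4, 2:4, 10:109] <- TRUE
  v <- voxel_volume(occ, spacing = 1)
  expect_equal(functional_length(v), 100)

  occ1 <- array(FALSE, dim = c(5, 5, 3))
  occ1[2:4, 2:4, 2] <- TRUE
  expect_equal(functional_length(voxel_volume(occ1, spacing = 0.5)), 0.5)
})

test_that("2x2 pixel slice matches the solid-square closed form", {
  v <- voxel_volume(array(TRUE, dim = c(2, 2, 1)), spacing = 1)
  p <- slice_profile(v)
  expect_equal(p$csa, 4)
  expect_equal(p$i_major, 16 / 12, tolerance = 1e-12)
  expect_equal(p$i_minor, 16 / 12, tolerance = 1e-12)
  expect_equal(p$compactness, 1)
})

test_that("solid ellipse principal moment ratio converges to (a/b)^2", {
  v <- voxelize_tube(L = 0.1, a = 4, b = 2, spacing = 0.02)
  p <- slice_profile(v)
  expect_equal(p$i_major[1] / p$i_minor[1], 4, tolerance = 0.01)
})

test_that("annulus compactness converges to 1 - (r/R)^2", {
  R <- 5
  v <- voxelize_tube(L = 0.3, a = R, b = R, inner_a = 0.6 * R, inner_b = 0.6 * R,
                     spacing = R / 50)
  p <- slice_profile(v)
  expect_equal(p$compactness[1], 0.64, tolerance = 0.01)
})

test_that("voxel moments converge monotonically to closed forms", {
  # error averaged over sub-voxel placements of the section, so a lucky
  # lattice alignment at one spacing cannot mask the convergence order
  a <- 4; b <- 2
  i_true <- pi * a^3 * b / 4
  offsets <- cbind(c(0, 0.31, 0.5, 0.73), c(0, 0.59, 0.5, 0.17))
  err <- vapply(c(b / 10, b / 20, b / 40), function(h) {
    mean(vapply(seq_len(nrow(offsets)), function(o) {
      nx <- 2L * ceiling(a / h) + 3L
      ny <- 2L * ceiling(b / h) + 3L
      xs <- (seq_len(nx) - (nx + 1) / 2 + offsets[o, 1]) * h
      ys <- (seq_len(ny) - (ny + 1) / 2 + offsets[o, 2]) * h
      mask <- outer(xs, ys, function(x, y) (x / a)^2 + (y / b)^2 <= 1)
      v <- voxel_volume(array(mask, dim = c(nx, ny, 1)), spacing = h)
      abs(slice_profile(v)$i_major - i_true) / i_true
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(err) < 0))
  expect_lt(err[3], 0.01)
})

test_that("middle 40% window and midshaft slice follow the center rule", {
  make_prof <- function(n_occupied, pad = 5L) {
    occ <- array(FALSE, dim = c(4, 4, n_occupied + 2L * pad))
    occ[2:3, 2:3, pad + seq_len(n_occupied)] <- TRUE
    v <- voxel_volume(occ, spacing = 1)
    list(p = slice_profile(v), L = functional_length(v), pad = pad)
  }
  x <- make_prof(100L)
  reg <- middle_region(x$p, x$L)
  expect_equal(range(reg$included - x$pad), c(31, 70))
  expect_equal(reg$midshaft - x$pad, 50)  # tie between 50/51 -> proximal

  x1 <- make_prof(101L)
  expect_equal(middle_region(x1$p, x1$L)$midshaft - x1$pad, 51)

  wide <- middle_region(x$p, x$L, fraction = 0.999)
  expect_equal(length(wide$included), 100L)
  expect_error(middle_region(x$p, x$L, fraction = 1), "fraction")
})

test_that("structure traits reproduce cylinder and tube closed forms", {
  cyl <- voxelize_tube(L = 100, a = 10, b = 10, spacing = 0.4)
  st <- structure_traits(slice_profile(cyl), functional_length(cyl))
  expect_equal(st$cg, 1)
  expect_equal(st$de, 10 / sqrt(pi), tolerance = 0.01)
  expect_equal(st$css, 1, tolerance = 0.01)

  tube <- voxelize_tube(L = 20, a = 5, b = 5, inner_a = 3, inner_b = 3,
                        spacing = 0.1)
  st2 <- structure_traits(slice_profile(tube), functional_length(tube))
  expect_equal(st2$cg, 0.64, tolerance = 0.01)
  expect_equal(st2$css, 1, tolerance = 0.01)

  ell <- voxelize_tube(L = 20, a = 4, b = 2, spacing = 2 / 25)
  st3 <- structure_traits(slice_profile(ell), functional_length(ell))
  expect_equal(st3$css, 4, tolerance = 0.02)
})

test_that("traits are invariant under 90-degree grid rotation and rescaling", {
  v <- voxelize_tube(L = 20, a = 4, b = 2.5, inner_a = 2, inner_b = 1.2,
                     spacing = 0.1)
  st <- structure_traits(slice_profile(v), functional_length(v))
  # 90-degree in-plane rotation: transpose the first two axes
  occ90 <- aperm(v$occupancy, c(2, 1, 3))
  v90 <- voxel_volume(occ90, spacing = v$spacing)
  st90 <- structure_traits(slice_profile(v90), functional_length(v90))
  expect_equal(st90$cg, st$cg, tolerance = 1e-12)
  expect_equal(st90$css, st$css, tolerance = 1e-12)
  expect_equal(st90$de, st$de, tolerance = 1e-12)
  # scaling object and spacing by k: identical grid, so dimensionless traits
  # are unchanged and CSA/I scale by k^2 and k^4
  k <- 3
  vk <- voxel_volume(v$occupancy, spacing = v$spacing * k)
  pk <- slice_profile(vk)
  p <- slice_profile(v)
  stk <- structure_traits(pk, functional_length(vk))
  expect_equal(stk$cg, st$cg)
  expect_equal(stk$de, st$de)
  expect_equal(stk$css, st$css)
  expect_equal(pk$csa, p$csa * k^2)
  expect_equal(pk$i_major, p$i_major * k^4)
})

test_that("oblique volumes reorient to within a few percent of axis-aligned", {
  st_of <- function(v) {
    ov <- orient_volume(v)
    structure_traits(slice_profile(ov), functional_length(ov))
  }
  s0 <- st_of(voxelize_rotated_tube(0))
  s30 <- st_of(voxelize_rotated_tube(30 * pi / 180))
  expect_equal(s30$cg, s0$cg, tolerance = 0.03)
  expect_equal(s30$de, s0$de, tolerance = 0.03)
  expect_equal(s30$css, s0$css, tolerance = 0.03)
  # 90-degree rotation about x maps onto the grid: slice counts match
  s90 <- st_of(voxelize_rotated_tube(pi / 2))
  expect_equal(s90$de, s0$de, tolerance = 0.01)
})

test_that("orientation leaves an axis-aligned volume unresampled", {
  v <- voxelize_tube(L = 30, a = 3, b = 2, spacing = 0.2)
  ov <- orient_volume(v)
  expect_equal(sum(ov$occupancy), sum(v$occupancy))
  expect_equal(dim(ov$occupancy), dim(v$occupancy))
})

test_that("near-spherical clouds are left as-is with a warning", {
  occ <- array(FALSE, dim = c(21, 21, 21))
  xs <- seq(-1, 1, length.out = 21)
  G <- expand.grid(xs, xs, xs)
  occ[rowSums(G^2) <= 1] <- TRUE
  v <- voxel_volume(occ, spacing = 0.1)
  expect_warning(ov <- orient_volume(v), "isotropic")
  expect_identical(ov$occupancy, v$occupancy)
})

test_that("batch_structure records failures and is deterministic", {
  v <- voxelize_tube(L = 15, a = 3, b = 2, spacing = 0.2)
  vols <- list(a = v, b = v, c = v)
  manifest <- data.frame(specimen = c("a", "b", "c", "missing"))
  out <- batch_structure(vols, manifest, orient = FALSE)
  expect_equal(nrow(out), 4L)
  expect_equal(sum(is.na(out$error)), 3L)
  expect_match(out$error[4], "missing")
  # same volume listed twice gives identical rows
  out2 <- batch_structure(vols, data.frame(specimen = c("a", "a")),
                          orient = FALSE)
  expect_equal(out2$css[1], out2$css[2])
  expect_true(all(out$css[1:3] >= 1))
})
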