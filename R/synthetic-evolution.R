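# Simulated comparative data with known ground truth: a pure-birth phylogeny,
# clade-clustered ecotypes, Brownian ln-size, structure traits following a
# per-ecotype regression with lambda-structured errors, and landmark shapes
# with an ecotype mean + allometric vector + Brownian deviation structure.

#' Simulate an ultrametric pure-birth phylogeny
#'
#' @param n_tips number of tips (>= 4).
#' @param seed RNG seed.
#' @return An `ape::phylo`, binary and ultrametric, tips relabeled
#'   `sp01, sp02, ...`.
#' @export
simulate_phylogeny <- function(n_tips, seed = NULL) {
  if (n_tips < 4L) stopf("need at least 4 tips")
  tree <- with_seed(seed, ape::rphylo(n_tips, birth = 1, death = 0))
  tree$tip.label <- sprintf("sp%02d", seq_len(n_tips))
  tree
}

#' Phylogenetic clustering index of a labeling
#'
#' Fraction of tips whose nearest neighbor on the tree (cophenetic distance,
#' ties resolved by the closest match in tip order) shares their label.
#'
#' @param tree `ape::phylo`.
#' @param labels named (or tip-ordered) label vector.
#' @return A number in `[0, 1]`.
#' @export
clustering_index <- function(tree, labels) {
  if (!is.null(names(labels))) labels <- labels[tree$tip.label]
  D <- ape::cophenetic.phylo(tree)
  diag(D) <- Inf
  nn <- apply(D, 1, which.min)
  mean(labels == labels[nn])
}

#' Paint clade-clustered ecotypes on a tree
#'
#' Labels are unions of whole clades: starting from a single background
#' label, randomly chosen internal nodes donate their descendant tips to new
#' (or, once all labels exist, existing) ecotypes, under the constraint that
#' every ecotype keeps at least `min_size` tips. This reproduces the
#' phylogenetic clustering of real locomotor ecotypes, which is what makes
#' lambda-aware and lambda-free analyses disagree.
#'
#' @param tree `ape::phylo`.
#' @param n_ecotypes number of ecotypes (>= 1).
#' @param clade_seeds number of internal nodes used to paint; must be
#'   `>= n_ecotypes - 1`.
#' @param seed RNG seed.
#' @param min_size minimum tips per ecotype, default 2.
#' @return Named factor of ecotype labels per tip. For 4 ecotypes the levels
#'   are the squirrel locomotor categories
#'   (chipmunk, gliding, ground, tree); otherwise `eco1, eco2, ...`.
#' @export
assign_clustered_ecotypes <- function(tree, n_ecotypes, clade_seeds = n_ecotypes - 1L,
                                      seed = NULL, min_size = 2L) {
  n <- length(tree$tip.label)
  if (n_ecotypes < 1L) stopf("n_ecotypes must be >= 1")
  if (n_ecotypes > clade_seeds + 1L) stopf("need clade_seeds >= n_ecotypes - 1")
  if (n_ecotypes * min_size > n) stopf("tree too small for %d ecotypes of >= %d tips",
                                       n_ecotypes, min_size)
  lev <- if (n_ecotypes == 4L) c("chipmunk", "gliding", "ground", "tree") else
    sprintf("eco%d", seq_len(n_ecotypes))
  lab <- rep(1L, n)
  if (n_ecotypes > 1L) {
    internal <- (n + 2L):(n + tree$Nnode)  # exclude the root
    clades <- lapply(internal, function(nd) {
      which(tree$tip.label %in% ape::extract.clade(tree, nd)$tip.label)
    })
    with_seed(seed, {
      painted <- 0L
      next_new <- 2L
      order_nodes <- sample(seq_along(internal))
      for (j in order_nodes) {
        if (painted >= clade_seeds) break
        tips_j <- clades[[j]]
        target <- if (next_new <= n_ecotypes) next_new else sample.int(n_ecotypes, 1L)
        cand <- lab
        cand[tips_j] <- target
        sizes <- tabulate(cand, nbins = n_ecotypes)
        used <- seq_len(min(next_new, n_ecotypes))
        if (all(sizes[used] >= min_size) && sizes[target] >= min_size &&
            length(unique(lab[tips_j])) == 1L && any(lab[tips_j] != target)) {
          lab <- cand
          painted <- painted + 1L
          if (target == next_new) next_new <- next_new + 1L
        }
      }
      if (next_new <= n_ecotypes) {
        stopf("could not paint %d ecotypes of >= %d tips from whole clades; tree clades too small",
              n_ecotypes, min_size)
      }
    })
  }
  stats::setNames(factor(lev[lab], levels = lev), tree$tip.label)
}

#' Simulation parameters for traits and shapes on a phylogeny
#'
#' Collects the generating parameters used by [simulate_traits()],
#' [simulate_shapes()] and [simulate_dataset()]. Per-ecotype intercepts and
#' slopes follow the linear model `y = beta0(ecotype) + beta1(ecotype) * ln
#' size + e`, with `e ~ N(0, sigma2 * C(lambda))`.
#'
#' @param n_tips,n_ecotypes,clade_seeds tree and labeling sizes.
#' @param traits named list; each element is a list with numeric `beta0` and
#'   `beta1` (length `n_ecotypes`), `sigma2 > 0` and `lambda` in `[0, 1]`.
#' @param size_root,size_sigma2 Brownian root state and rate for ln size.
#' @param shape_allometry scalar multiplier for the built-in allometric
#'   landmark displacement (mm per unit ln size).
#' @param shape_sigma2 Brownian rate of per-coordinate shape deviations.
#' @param shape_ecotype_scale size of ecotype mean-shape offsets, mm.
#' @param n_theta,n_z landmark grid of the template bone.
#' @param seed master RNG seed.
#' @return A list of class `evol_params`.
#' @export
evol_params <- function(n_tips = 76L, n_ecotypes = 4L, clade_seeds = 6L,
                        traits = default_trait_params(n_ecotypes),
                        size_root = 3.0, size_sigma2 = 0.5,
                        shape_allometry = 0.08, shape_sigma2 = 1e-4,
                        shape_ecotype_scale = 0.35,
                        n_theta = 10L, n_z = 6L, seed = 1L) {
  for (nm in names(traits)) {
    tr <- traits[[nm]]
    if (length(tr$beta0) != n_ecotypes || length(tr$beta1) != n_ecotypes) {
      stopf("trait '%s' needs beta0/beta1 of length n_ecotypes", nm)
    }
    if (tr$sigma2 < 0) stopf("trait '%s': sigma2 must be >= 0", nm)
    if (tr$lambda < 0 || tr$lambda > 1) stopf("trait '%s': lambda must be in [0, 1]", nm)
  }
  structure(
    list(n_tips = n_tips, n_ecotypes = n_ecotypes, clade_seeds = clade_seeds,
         traits = traits, size_root = size_root, size_sigma2 = size_sigma2,
         shape_allometry = shape_allometry, shape_sigma2 = shape_sigma2,
         shape_ecotype_scale = shape_ecotype_scale,
         n_theta = n_theta, n_z = n_z, seed = seed),
    class = "evol_params"
  )
}

#' Default generating parameters for the three structure traits
#'
#' Ecotype-specific intercepts and slopes of plausible magnitude for Cg, DE
#' and CSS (all dimensionless), with moderate phylogenetic signal in the
#' residuals.
#'
#' @param n_ecotypes number of ecotypes.
#' @return Named list suitable for [evol_params()].
#' @export
default_trait_params <- function(n_ecotypes = 4L) {
  rep4 <- function(x) rep_len(x, n_ecotypes)
  list(
    cg = list(beta0 = rep4(c(0.55, 0.60, 0.70, 0.62)),
              beta1 = rep4(c(0.02, -0.03, 0.05, 0.00)),
              sigma2 = 0.0025, lambda = 0.5),
    de = list(beta0 = rep4(c(17.3, 22.4, 14.8, 16.9)),
              beta1 = rep4(c(0.0, 1.4, -1.1, -2.1)),
              sigma2 = 1.0, lambda = 0.3),
    css = list(beta0 = rep4(c(1.26, 1.26, 1.71, 1.45)),
               beta1 = rep4(c(0.37, 0.02, 0.42, 0.21)),
               sigma2 = 0.01, lambda = 0.5)
  )
}

# draw one MVN vector with covariance sigma2 * C(lambda) from the tree
rmvn_lambda <- function(C, sigma2, lambda) {
  Cl <- lambda * C
  diag(Cl) <- diag(C)
  drop(crossprod(chol(sigma2 * Cl), stats::rnorm(nrow(C))))
}

#' Simulate ln size and structure traits on a tree
#'
#' ln size evolves as Brownian motion from `size_root`; each trait follows
#' `y = beta0(ecotype) + beta1(ecotype) * lnsize + e` with
#' `e ~ N(0, sigma2 * C(lambda))`, where `C` is the Brownian covariance of
#' the tree and lambda scales its off-diagonals.
#'
#' @param tree `ape::phylo`.
#' @param ecotypes named factor from [assign_clustered_ecotypes()].
#' @param params an [evol_params()].
#' @param seed RNG seed (defaults to `params$seed`).
#' @return A data.frame (rownames = tips) with `ecotype`, `lnsize` and one
#'   column per trait; the generating parameters are attached as
#'   `attr(, "ground_truth")`.
#' @export
simulate_traits <- function(tree, ecotypes, params, seed = params$seed) {
  ecotypes <- ecotypes[tree$tip.label]
  C <- ape::vcv(tree)
  eco_idx <- as.integer(ecotypes)
  out <- with_seed(seed, {
    lnsize <- params$size_root + rmvn_lambda(C, params$size_sigma2, 1)
    df <- data.frame(ecotype = ecotypes, lnsize = lnsize,
                     row.names = tree$tip.label)
    for (nm in names(params$traits)) {
      tr <- params$traits[[nm]]
      eps <- if (tr$sigma2 > 0) rmvn_lambda(C, tr$sigma2, tr$lambda) else 0
      df[[nm]] <- tr$beta0[eco_idx] + tr$beta1[eco_idx] * lnsize + eps
    }
    df
  })
  attr(out, "ground_truth") <- params$traits
  out
}

# template landmark configuration and allometric displacement field
shape_template <- function(params) {
  spec <- bone_spec(L = 30, a_mid = 3, b_mid = 2.4, t = 1, flare = 0.4)
  base <- make_synthetic_bone(spec, spacing = 0.45,
                              n_theta = params$n_theta, n_z = params$n_z)$landmarks
  k <- nrow(base)
  # allometric field: radial widening growing toward the ends
  r <- sqrt(base[, 1]^2 + base[, 2]^2)
  u <- 2 * base[, 3] / max(base[, 3]) - 1
  v <- cbind(base[, 1] / r * (0.5 + u^2), base[, 2] / r * (0.5 + u^2), 0.2 * u)
  list(base = base, allometry = v, k = k)
}

#' Simulate corresponding landmark configurations on a tree
#'
#' Each tip's configuration is
#' `mean_shape(ecotype) + lnsize * allometry_vector + Brownian deviation`,
#' with deviations independent across landmarks and axes but tree-structured
#' across tips.
#'
#' @param tree `ape::phylo`.
#' @param ecotypes named factor per tip.
#' @param lnsize named numeric per tip (e.g. from [simulate_traits()]).
#' @param params an [evol_params()].
#' @param seed RNG seed (defaults to `params$seed + 1`).
#' @param mean_shapes optional list of `k x 3` ecotype mean shapes (must share
#'   landmark count and order); defaults to a template bone plus seeded
#'   ecotype offsets.
#' @param allometry optional `k x 3` allometric displacement per unit ln size.
#' @return A [landmark_sample()]; ground truth attached as attributes.
#' @export
simulate_shapes <- function(tree, ecotypes, lnsize, params,
                            seed = params$seed + 1L,
                            mean_shapes = NULL, allometry = NULL) {
  ecotypes <- ecotypes[tree$tip.label]
  lnsize <- lnsize[tree$tip.label]
  tmpl <- shape_template(params)
  k <- tmpl$k
  levs <- levels(ecotypes)

  if (is.null(allometry)) allometry <- params$shape_allometry * tmpl$allometry
  if (!all(dim(allometry) == c(k, 3))) stopf("allometry must be k x 3")

  if (is.null(mean_shapes)) {
    mean_shapes <- with_seed(stage_seed(seed, "ecotype-means"), {
      lapply(seq_along(levs), function(e) {
        tmpl$base + params$shape_ecotype_scale *
          matrix(stats::rnorm(k * 3), k, 3)
      })
    })
    names(mean_shapes) <- levs
  }
  dims <- vapply(mean_shapes, function(m) paste(dim(m), collapse = "x"), character(1))
  if (length(unique(dims)) != 1L || !all(dim(mean_shapes[[1]]) == c(k, 3))) {
    stopf("ecotype mean shapes must all be %d x 3", k)
  }

  C <- ape::vcv(tree)
  n <- length(tree$tip.label)
  coords <- array(NA_real_, dim = c(n, k, 3))
  dev <- with_seed(seed, {
    if (params$shape_sigma2 > 0) {
      R <- chol(params$shape_sigma2 * C)
      crossprod(R, matrix(stats::rnorm(n * k * 3), n, k * 3))
    } else {
      matrix(0, n, k * 3)
    }
  })
  for (i in seq_len(n)) {
    coords[i, , ] <- mean_shapes[[as.integer(ecotypes[i])]] +
      lnsize[i] * allometry + matrix(dev[i, ], k, 3)
  }
  out <- landmark_sample(coords, specimens = tree$tip.label,
                         landmarks = rownames(tmpl$base))
  attr(out, "mean_shapes") <- mean_shapes
  attr(out, "allometry") <- allometry
  out
}

#' Simulate a complete synthetic dataset
#'
#' Tree, clade-clustered ecotypes, ln size, structure traits, landmark
#' shapes, and one bone specification per tip (scaled by size, cross-section
#' flattened per ecotype so cross-sectional shape varies). All randomness
#' flows from `params$seed` through stage-scoped streams; the same seed gives
#' a bit-identical dataset.
#'
#' @param params an [evol_params()].
#' @return A list of class `simulated_dataset`: `tree`, `specimens`
#'   (data.frame with ecotype, lnsize and traits), `shapes`
#'   ([landmark_sample()]), `bone_specs` (list of [bone_spec()]),
#'   `ground_truth`.
#' @export
simulate_dataset <- function(params = evol_params()) {
  tree <- simulate_phylogeny(params$n_tips, seed = stage_seed(params$seed, "tree"))
  eco <- assign_clustered_ecotypes(tree, params$n_ecotypes, params$clade_seeds,
                                   seed = stage_seed(params$seed, "ecotypes"))
  traits <- simulate_traits(tree, eco, params,
                            seed = stage_seed(params$seed, "traits"))
  shapes <- simulate_shapes(tree, eco, stats::setNames(traits$lnsize, rownames(traits)),
                            params, seed = stage_seed(params$seed, "shapes"))
  # per-tip bone geometry: overall scale follows size; ecotype flattens the
  # midshaft ellipse so voxel-measured CSS differs among ecotypes; the femur
  # is longer and rounder than the humerus
  scale <- exp(traits$lnsize - mean(traits$lnsize))
  eco_i <- as.integer(eco)
  make_specs <- function(L0, b0, t0, ratios) {
    specs <- lapply(seq_len(params$n_tips), function(i) {
      b <- b0 * scale[i]
      bone_spec(L = L0 * scale[i], a_mid = b * ratios[eco_i[i]], b_mid = b,
                t = t0 * scale[i], flare = 0.4)
    })
    names(specs) <- tree$tip.label
    specs
  }
  specs <- list(
    humerus = make_specs(28, 2.2, 0.85, rep_len(c(1.15, 1.10, 1.60, 1.35), params$n_ecotypes)),
    femur = make_specs(33, 2.3, 0.9, rep_len(c(1.10, 1.05, 1.30, 1.20), params$n_ecotypes))
  )
  structure(
    list(tree = tree, specimens = traits, shapes = shapes, bone_specs = specs,
         ground_truth = list(params = params,
                             trait_params = attr(traits, "ground_truth"),
                             mean_shapes = attr(shapes, "mean_shapes"),
                             allometry = attr(shapes, "allometry"))),
    class = "simulated_dataset"
  )
}

#' @export
print.simulated_dataset <- function(x, ...) {
  cat(sprintf("<simulated_dataset> %d tips, ecotypes: %s\n",
              length(x$tree$tip.label),
              paste(levels(x$specimens$ecotype), collapse = ", ")))
  invisible(x)
}
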