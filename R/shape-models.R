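# Multivariate linear models on shape (or trait) matrices with residual
# randomization, plus ordination and classification tools.

# inverse symmetric square root of a covariance matrix
inv_sqrt_mat <- function(C) {
  e <- eigen(C, symmetric = TRUE)
  if (min(e$values) <= 0) stopf("phylogenetic covariance is not positive definite")
  e$vectors %*% (t(e$vectors) / sqrt(e$values))
}

# resolve the phylogenetic projection for a set of specimen ids
phylo_projection <- function(phylo, tree, lambda, ids) {
  phylo <- match.arg(phylo, c("none", "BM", "lambda"))
  if (phylo == "none") return(NULL)
  if (is.null(tree)) stopf("phylo = '%s' needs a tree", phylo)
  lam <- if (phylo == "BM") 1 else lambda
  C <- phylo_covariance(tree, lam)
  miss <- setdiff(ids, rownames(C))
  if (length(miss)) stopf("tree is missing tips: %s", paste(miss, collapse = ", "))
  inv_sqrt_mat(C[ids, ids])
}

# all permutations of 1..n (n small), as a list
all_perms <- function(n) {
  if (n > 8L) stopf("exhaustive permutation only supported for n <= 8")
  if (n == 1L) return(list(1L))
  sub <- all_perms(n - 1L)
  out <- vector("list", n * length(sub))
  m <- 0L
  for (s in sub) {
    for (pos in seq_len(n)) {
      m <- m + 1L
      out[[m]] <- append(s, n, after = pos - 1L)
    }
  }
  out
}

# Shared engine: sequential (type I) multivariate linear model with residual
# randomization of the reduced model per term. statistic = "F" gives the
# Procrustes/Goodall-style F on summed squares; "pillai" gives Pillai's trace.
rrpp_engine <- function(Y, formula, data, n_perm = 999L, seed = NULL,
                        phylo = "none", tree = NULL, lambda = 1,
                        statistic = c("F", "pillai")) {
  statistic <- match.arg(statistic)
  Y <- as.matrix(Y)
  n <- nrow(Y)
  if (!is.null(rownames(Y)) && all(rownames(Y) %in% rownames(data))) {
    data <- data[rownames(Y), , drop = FALSE]
  }
  if (nrow(data) != n) stopf("data rows must match rows of Y")

  mt <- stats::terms(formula)
  X <- stats::model.matrix(mt, data)
  asgn <- attr(X, "assign")
  labels <- attr(mt, "term.labels")
  n_terms <- length(labels)
  if (n_terms == 0L) stopf("model has no terms to test")
  if (qr(X)$rank < ncol(X)) stopf("rank-deficient design; check terms: %s",
                                  paste(labels, collapse = ", "))

  ids <- rownames(Y) %||% rownames(data)
  P <- phylo_projection(phylo, tree, lambda, ids)
  if (!is.null(P)) {
    Y <- P %*% Y
    X <- P %*% X
  }
  p <- ncol(Y)
  if (statistic == "pillai" && p > n - ncol(X)) {
    stopf("Pillai's trace needs fewer variables (%d) than residual df (%d); reduce by PCA first",
          p, n - ncol(X))
  }

  # nested designs: intercept-only, then adding one term at a time
  Qs <- lapply(0:n_terms, function(i) {
    qr.Q(qr(X[, asgn <= i, drop = FALSE]))
  })
  dfs <- vapply(0:n_terms, function(i) sum(asgn <= i), integer(1))
  df_res <- n - dfs[n_terms + 1L]
  if (df_res < 1L) stopf("no residual degrees of freedom")

  rss_of <- function(Q, Yw) sum(Yw^2) - sum(crossprod(Q, Yw)^2)
  resid_cp <- function(Q, Yw) {
    Fit <- Q %*% crossprod(Q, Yw)
    E <- Yw - Fit
    crossprod(E)
  }

  stat_term <- function(Yw, i) {
    if (statistic == "F") {
      ss_i <- rss_of(Qs[[i]], Yw) - rss_of(Qs[[i + 1L]], Yw)
      ss_res <- rss_of(Qs[[n_terms + 1L]], Yw)
      df_i <- dfs[i + 1L] - dfs[i]
      (ss_i / df_i) / (ss_res / df_res)
    } else {
      H <- resid_cp(Qs[[i]], Yw) - resid_cp(Qs[[i + 1L]], Yw)
      E <- resid_cp(Qs[[n_terms + 1L]], Yw)
      # pseudoinverse so degenerate (duplicated-column) responses still work
      s <- svd(H + E)
      pos <- s$d > max(s$d) * 1e-12
      inv <- s$v[, pos, drop = FALSE] %*%
        (t(s$u[, pos, drop = FALSE]) / s$d[pos])
      sum(diag(H %*% inv))
    }
  }

  exhaustive <- identical(n_perm, "exhaustive")
  perms <- if (exhaustive) {
    all_perms(n)
  } else {
    with_seed(seed, replicate(n_perm, sample.int(n), simplify = FALSE))
  }

  ss_total <- rss_of(Qs[[1L]], Y)
  out <- vector("list", n_terms)
  for (i in seq_len(n_terms)) {
    obs <- stat_term(Y, i)
    ss_i <- rss_of(Qs[[i]], Y) - rss_of(Qs[[i + 1L]], Y)
    # permute residuals of the reduced (term-excluded) model
    Q_red <- Qs[[i]]
    Fit_red <- Q_red %*% crossprod(Q_red, Y)
    E_red <- Y - Fit_red
    null_stats <- vapply(perms, function(pm) {
      stat_term(Fit_red + E_red[pm, , drop = FALSE], i)
    }, numeric(1))
    pval <- if (exhaustive) {
      mean(null_stats >= obs - 1e-12)
    } else {
      (1 + sum(null_stats >= obs - 1e-12)) / (length(perms) + 1)
    }
    z <- (obs - mean(null_stats)) / stats::sd(null_stats)
    out[[i]] <- data.frame(
      term = labels[i], df = dfs[i + 1L] - dfs[i], SS = ss_i,
      R2 = ss_i / ss_total, statistic = obs, Z = z, p = pval
    )
  }
  table <- do.call(rbind, out)
  names(table)[names(table) == "statistic"] <- if (statistic == "F") "F" else "pillai"

  structure(
    list(table = table, statistic = statistic, formula = formula,
         n_perm = if (exhaustive) length(perms) else n_perm, seed = seed,
         exhaustive = exhaustive, phylo = phylo, lambda = lambda,
         Y = Y, X = X, assign = asgn, term_labels = labels, data = data,
         df_res = df_res, mt = mt),
    class = "rrpp_fit"
  )
}

#' @export
print.rrpp_fit <- function(x, ...) {
  cat(sprintf("Residual-randomization %s model: %s (%s permutations%s)\n",
              if (x$statistic == "F") "Procrustes" else "Pillai MANOVA",
              deparse(x$formula), x$n_perm,
              if (x$phylo != "none") paste0(", phylo = ", x$phylo) else ""))
  print(x$table, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Procrustes ANOVA/ANCOVA with residual randomization (RRPP)
#'
#' Linear model on a multivariate response (aligned shape coordinates or any
#' trait matrix) with sums of squares computed sequentially from nested fits
#' and significance assessed by the residual randomization permutation
#' procedure: for each term, residuals of the model excluding that term are
#' permuted, added back to the reduced fitted values, and the term's F is
#' recomputed; `p = (1 + #{F* >= F}) / (n_perm + 1)` and
#' `Z = (F - mean(F*)) / sd(F*)`.
#'
#' With `phylo = "BM"` or `"lambda"`, response and design are premultiplied by
#' the inverse symmetric square root of the (lambda-scaled) phylogenetic
#' covariance before fitting, giving a phylogenetic Procrustes ANCOVA.
#'
#' @param Y numeric matrix (n specimens x p variables) or an `aligned_sample`.
#' @param formula right-hand-side formula over columns of `data`,
#'   e.g. `~ lnsize * ecotype`.
#' @param data data.frame of predictors; rows match `Y` (by rowname when
#'   available).
#' @param n_perm number of permutations, or `"exhaustive"` (n <= 8).
#' @param seed RNG seed for the permutations.
#' @param phylo `"none"`, `"BM"` (Brownian, lambda = 1) or `"lambda"`.
#' @param tree `ape::phylo` tree when `phylo != "none"`.
#' @param lambda Pagel's lambda for `phylo = "lambda"`.
#' @return An `rrpp_fit` with a per-term table of df, SS, R2, F, Z, p.
#' @export
procrustes_lm <- function(Y, formula, data, n_perm = 999L, seed = NULL,
                          phylo = c("none", "BM", "lambda"), tree = NULL,
                          lambda = 1) {
  if (inherits(Y, "aligned_sample")) Y <- as_shape_matrix(Y)
  rrpp_engine(Y, formula, data, n_perm, seed, match.arg(phylo), tree, lambda,
              statistic = "F")
}

#' Pillai's-trace MANOVA with residual randomization
#'
#' Sequential multivariate tests using Pillai's trace computed from the
#' hypothesis and error cross-product matrices, with the same residual
#' randomization scheme (and optional phylogenetic transform) as
#' [procrustes_lm()]. Requires fewer response variables than residual
#' degrees of freedom; reduce shape data by PCA first if necessary.
#'
#' @inheritParams procrustes_lm
#' @return An `rrpp_fit` with a per-term table of df, SS, R2, pillai, Z, p.
#' @export
pillai_manova <- function(Y, formula, data, n_perm = 999L, seed = NULL,
                          phylo = c("none", "BM", "lambda"), tree = NULL,
                          lambda = 1) {
  if (inherits(Y, "aligned_sample")) Y <- as_shape_matrix(Y)
  rrpp_engine(Y, formula, data, n_perm, seed, match.arg(phylo), tree, lambda,
              statistic = "pillai")
}

#' Pairwise group comparisons from a fitted RRPP model
#'
#' Computes Euclidean distances between group least-squares means (numeric
#' covariates held at their means) and builds each distance's null
#' distribution by permuting residuals of the reduced model with every term
#' involving the group factor removed.
#'
#' @param fit an `rrpp_fit` from [procrustes_lm()] whose model contains
#'   `group`.
#' @param group name of the grouping factor in the model.
#' @param n_perm permutations (or `"exhaustive"`, n <= 8).
#' @param seed RNG seed.
#' @return A data.frame of unordered pairs with `distance`, `Z`, `p`; groups
#'   with a single member are flagged.
#' @export
pairwise_groups <- function(fit, group, n_perm = 999L, seed = NULL) {
  stopifnot(inherits(fit, "rrpp_fit"))
  if (!group %in% names(fit$data)) stopf("'%s' is not a model variable", group)
  g <- factor(fit$data[[group]])
  levels_g <- levels(g)
  if (length(levels_g) < 2L) stopf("need at least 2 groups")

  # prediction rows: covariates at their means, factor at each level
  newdata <- fit$data[rep(1L, length(levels_g)), , drop = FALSE]
  for (v in names(newdata)) {
    if (is.numeric(newdata[[v]])) newdata[[v]] <- mean(fit$data[[v]])
  }
  newdata[[group]] <- factor(levels_g, levels = levels_g)
  Lmat <- stats::model.matrix(stats::delete.response(fit$mt), newdata)

  X <- fit$X
  Y <- fit$Y
  qr_full <- qr(X)
  lsmeans_of <- function(Yw) {
    B <- qr.coef(qr_full, Yw)
    Lmat %*% B
  }
  dist_of <- function(M) as.matrix(stats::dist(M))

  obs <- dist_of(lsmeans_of(Y))

  involves <- vapply(fit$term_labels, function(tl) {
    group %in% all.vars(stats::as.formula(paste("~", tl)))
  }, logical(1))
  keep_terms <- which(!involves)
  X_red <- X[, fit$assign %in% c(0L, keep_terms), drop = FALSE]
  Q_red <- qr.Q(qr(X_red))
  Fit_red <- Q_red %*% crossprod(Q_red, Y)
  E_red <- Y - Fit_red

  exhaustive <- identical(n_perm, "exhaustive")
  perms <- if (exhaustive) all_perms(nrow(Y)) else {
    with_seed(seed, replicate(n_perm, sample.int(nrow(Y)), simplify = FALSE))
  }
  null_d <- array(NA_real_, dim = c(length(levels_g), length(levels_g), length(perms)))
  for (m in seq_along(perms)) {
    null_d[, , m] <- dist_of(lsmeans_of(Fit_red + E_red[perms[[m]], , drop = FALSE]))
  }

  pairs <- utils::combn(seq_along(levels_g), 2)
  res <- lapply(seq_len(ncol(pairs)), function(j) {
    a <- pairs[1, j]; b <- pairs[2, j]
    d_obs <- obs[a, b]
    d_null <- null_d[a, b, ]
    pval <- if (exhaustive) mean(d_null >= d_obs - 1e-12) else {
      (1 + sum(d_null >= d_obs - 1e-12)) / (length(perms) + 1)
    }
    data.frame(
      group1 = levels_g[a], group2 = levels_g[b], distance = d_obs,
      Z = (d_obs - mean(d_null)) / stats::sd(d_null), p = pval,
      singleton = sum(g == levels_g[a]) < 2L || sum(g == levels_g[b]) < 2L
    )
  })
  do.call(rbind, res)
}

#' Two-block partial least squares
#'
#' Singular decomposition of the cross-covariance between two centered blocks
#' measured on the same specimens; `r_PLS` is the absolute correlation of the
#' first pair of block scores, tested by permuting specimen order of the
#' second block.
#'
#' @param X,Y numeric matrices with matching rows (specimens).
#' @param n_perm number of permutations.
#' @param seed RNG seed.
#' @return A list of class `pls_result`: `r_pls`, `Z`, `p`, singular axes
#'   (`x_axis`, `y_axis`) and block scores.
#' @export
two_block_pls <- function(X, Y, n_perm = 999L, seed = NULL) {
  if (inherits(X, "aligned_sample")) X <- as_shape_matrix(X)
  if (inherits(Y, "aligned_sample")) Y <- as_shape_matrix(Y)
  X <- as.matrix(X); Y <- as.matrix(Y)
  n <- nrow(X)
  if (nrow(Y) != n) stopf("blocks must share specimens")
  Xc <- scale(X, center = TRUE, scale = FALSE)
  Yc <- scale(Y, center = TRUE, scale = FALSE)
  if (all(abs(Xc) < 1e-14) || all(abs(Yc) < 1e-14)) stopf("a block has zero variance")

  r_first <- function(Yp) {
    s <- svd(crossprod(Xc, Yp) / (n - 1), nu = 1, nv = 1)
    u <- Xc %*% s$u
    v <- Yp %*% s$v
    abs(stats::cor(u, v)[1, 1])
  }
  s <- svd(crossprod(Xc, Yc) / (n - 1), nu = 1, nv = 1)
  scores_x <- drop(Xc %*% s$u)
  scores_y <- drop(Yc %*% s$v)
  r_obs <- abs(stats::cor(scores_x, scores_y))

  null_r <- with_seed(seed, vapply(seq_len(n_perm), function(i) {
    r_first(Yc[sample.int(n), , drop = FALSE])
  }, numeric(1)))
  p <- (1 + sum(null_r >= r_obs - 1e-12)) / (n_perm + 1)
  z <- (r_obs - mean(null_r)) / stats::sd(null_r)
  structure(
    list(r_pls = r_obs, Z = z, p = p, n_perm = n_perm, seed = seed,
         x_axis = drop(s$u), y_axis = drop(s$v),
         scores_x = scores_x, scores_y = scores_y),
    class = "pls_result"
  )
}

#' @export
print.pls_result <- function(x, ...) {
  cat(sprintf("Two-block PLS: r_PLS = %.4f, Z = %.3f, p = %.4g (%d permutations)\n",
              x$r_pls, x$Z, x$p, x$n_perm))
  invisible(x)
}

#' Canonical variate analysis with jackknife cross-validation
#'
#' Projects the data onto leading principal components (enough to capture
#' `var_threshold` of the variance, or `retained_dims` if given, always fewer
#' than `n - g`), computes canonical axes from the between-group versus
#' pooled within-group eigenproblem, and evaluates classification by
#' leave-one-out: each specimen is classified to the nearest group by
#' Mahalanobis distance under group means and pooled covariance recomputed
#' without it. Exact distance ties go to the smaller group index.
#'
#' @param data numeric matrix (n x p) or `aligned_sample`.
#' @param groups factor (or coercible) of length n, each level with >= 2
#'   members.
#' @param retained_dims optional number of PCs to keep.
#' @param var_threshold PC variance fraction retained when `retained_dims` is
#'   `NULL`, default 0.95.
#' @return A list of class `cva_result`: `axes` (canonical axes in PC space),
#'   `scores`, `per_group_accuracy` (%), `overall_accuracy` (%),
#'   `assignments`, `retained_dims`.
#' @export
cva_jackknife <- function(data, groups, retained_dims = NULL,
                          var_threshold = 0.95) {
  if (inherits(data, "aligned_sample")) data <- as_shape_matrix(data)
  data <- as.matrix(data)
  g <- factor(groups)
  n <- nrow(data)
  ng <- nlevels(g)
  if (ng < 2L) stopf("need at least 2 groups")
  if (any(table(g) < 2L)) stopf("each group needs at least 2 members")

  pc <- stats::prcomp(data, center = TRUE, scale. = FALSE)
  pos <- which(pc$sdev^2 > 1e-12 * pc$sdev[1]^2)
  cume <- cumsum(pc$sdev[pos]^2) / sum(pc$sdev[pos]^2)
  r <- if (is.null(retained_dims)) which(cume >= var_threshold)[1] else retained_dims
  r_max <- min(length(pos), n - ng)
  if (r > r_max) {
    warnf("retained dimensions reduced from %d to %d (need < n - g)", r, r_max)
    r <- r_max
  }
  S <- pc$x[, seq_len(r), drop = FALSE]

  grand <- colMeans(S)
  means <- rowsum(S, g) / as.vector(table(g))
  W <- matrix(0, r, r)
  for (lv in levels(g)) {
    Sg <- S[g == lv, , drop = FALSE]
    W <- W + crossprod(sweep(Sg, 2, colMeans(Sg)))
  }
  W <- W / (n - ng)
  B <- crossprod(sweep(means, 2, grand) * sqrt(as.vector(table(g))))
  ev <- eigen(solve(W, B))
  n_axes <- min(ng - 1L, r)
  axes <- Re(ev$vectors[, seq_len(n_axes), drop = FALSE])

  assign_loo <- vapply(seq_len(n), function(i) {
    Si <- S[-i, , drop = FALSE]
    gi <- g[-i]
    mi <- rowsum(Si, gi) / as.vector(table(gi))
    Wi <- matrix(0, r, r)
    for (lv in levels(g)) {
      Sg <- Si[gi == lv, , drop = FALSE]
      Wi <- Wi + crossprod(sweep(Sg, 2, colMeans(Sg)))
    }
    Wi <- Wi / (n - 1L - ng)
    Wi_inv <- solve(Wi)
    d2 <- vapply(seq_len(ng), function(k) {
      v <- S[i, ] - mi[k, ]
      drop(v %*% Wi_inv %*% v)
    }, numeric(1))
    which(d2 <= min(d2) + 1e-12)[1]
  }, integer(1))
  assigned <- factor(levels(g)[assign_loo], levels = levels(g))

  correct <- assigned == g
  per_group <- stats::setNames(
    100 * as.numeric(tapply(correct, g, mean)), levels(g)
  )
  overall <- 100 * mean(correct)
  structure(
    list(axes = axes, scores = S %*% axes,
         per_group_accuracy = per_group, overall_accuracy = overall,
         assignments = assigned, retained_dims = r, groups = g),
    class = "cva_result"
  )
}

#' @export
print.cva_result <- function(x, ...) {
  cat(sprintf("CVA (jackknife): overall accuracy %.1f%% on %d PCs\n",
              x$overall_accuracy, x$retained_dims))
  print(round(x$per_group_accuracy, 1))
  invisible(x)
}

#' Shape PCA and phylomorphospace projection
#'
#' Principal components of the (flattened) aligned coordinates. When a tree
#' is supplied, shapes at internal nodes are reconstructed by generalized
#' least squares under Brownian motion and projected onto the same axes,
#' giving a phylomorphospace.
#'
#' @param aligned an `aligned_sample` or numeric matrix (n x p).
#' @param tree optional `ape::phylo` whose tips match specimen ids.
#' @param n_axes number of PC axes to return scores for (default all
#'   positive-variance axes).
#' @return A list of class `shape_pca`: `scores`, `eigenvalues`,
#'   `percent_variance`, `rotation`, `center`, and `node_scores` (NULL
#'   without a tree).
#' @export
shape_pca <- function(aligned, tree = NULL, n_axes = NULL) {
  M <- if (inherits(aligned, "aligned_sample")) as_shape_matrix(aligned) else as.matrix(aligned)
  if (nrow(M) < 2L) stopf("PCA needs at least 2 specimens")
  pc <- stats::prcomp(M, center = TRUE, scale. = FALSE)
  ev <- pc$sdev^2
  keep <- if (is.null(n_axes)) which(ev > 1e-12 * ev[1]) else seq_len(n_axes)
  node_scores <- NULL
  if (!is.null(tree)) {
    ids <- rownames(M)
    if (is.null(ids) || !all(tree$tip.label %in% ids)) {
      stopf("tree tips must match specimen ids")
    }
    sc <- pc$x[tree$tip.label, keep, drop = FALSE]
    node_scores <- vapply(seq_len(ncol(sc)), function(j) {
      ancestral_states(tree, sc[, j])
    }, numeric(tree$Nnode))
    node_scores <- matrix(node_scores, nrow = tree$Nnode,
                          dimnames = list(
                            as.character(seq_len(tree$Nnode) + length(tree$tip.label)),
                            colnames(sc)
                          ))
  }
  structure(
    list(scores = pc$x[, keep, drop = FALSE], eigenvalues = ev,
         percent_variance = 100 * ev / sum(ev), rotation = pc$rotation,
         center = pc$center, node_scores = node_scores),
    class = "shape_pca"
  )
}

#' GLS (maximum-likelihood) ancestral states under Brownian motion
#'
#' Conditional expectation of internal-node states given tip values, with the
#' root at its generalized-least-squares estimate; on a star phylogeny the
#' root equals the tip mean.
#'
#' @param tree `ape::phylo`.
#' @param y named numeric vector of tip values.
#' @return Numeric vector of states for internal nodes (root first, in
#'   `ape` node order).
#' @export
ancestral_states <- function(tree, y) {
  y <- y[tree$tip.label]
  n <- length(tree$tip.label)
  root <- n + 1L
  D <- ape::dist.nodes(tree)
  nodes <- seq_len(tree$Nnode) + n
  depth <- D[root, ]
  shared <- function(i, j) (depth[i] + depth[j] - D[i, j]) / 2
  Ctt <- outer(seq_len(n), seq_len(n), Vectorize(shared))
  Cat <- outer(nodes, seq_len(n), Vectorize(shared))
  Ci <- solve(Ctt)
  one <- rep(1, n)
  mu <- drop((one %*% Ci %*% y) / (one %*% Ci %*% one))
  drop(mu + Cat %*% Ci %*% (y - mu))
}
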