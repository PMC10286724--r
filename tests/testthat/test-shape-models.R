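test_that("univariate RRPP model reproduces the classical ANOVA table", {
  set.seed(10)
  n <- 24
  df <- data.frame(x = rnorm(n), g = factor(rep(letters[1:3], n / 3)))
  y <- matrix(1 + 0.5 * df$x + (df$g == "b") * 0.8 + rnorm(n), ncol = 1)
  fit <- procrustes_lm(y, ~ x + g, df, n_perm = 199, seed = 1)
  a <- anova(lm(y ~ x + g, df))
  expect_equal(fit$table$F, a$`F value`[1:2], tolerance = 1e-12)
  expect_equal(fit$table$SS, a$`Sum Sq`[1:2], tolerance = 1e-12)
  # permutation p approaches the parametric p for the strong group term
  fit2 <- procrustes_lm(y, ~ x + g, df, n_perm = 4999, seed = 1)
  expect_equal(fit2$table$p[2], a$`Pr(>F)`[2], tolerance = 0.02)
})

test_that("sampled RRPP p-values agree with exhaustive enumeration at n = 5", {
  set.seed(2)
  df <- data.frame(x = rnorm(5))
  y <- matrix(df$x + rnorm(5, sd = 0.8), ncol = 1)
  ex <- procrustes_lm(y, ~ x, df, n_perm = "exhaustive")
  sm <- procrustes_lm(y, ~ x, df, n_perm = 9999, seed = 3)
  expect_equal(sm$table$p, ex$table$p, tolerance = 0.02)
  expect_equal(ex$n_perm, factorial(5))
})

test_that("phylogenetic transform changes the fit in the expected direction", {
  ds <- small_dataset()
  df <- ds$specimens
  y <- matrix(df$de, dimnames = list(rownames(df), NULL))
  f0 <- procrustes_lm(y, ~ ecotype, df, n_perm = 99, seed = 1)
  fb <- procrustes_lm(y, ~ ecotype, df, n_perm = 99, seed = 1,
                      phylo = "BM", tree = ds$tree)
  # clustered ecotypes: accounting for the tree absorbs group variance
  expect_lt(fb$table$R2, f0$table$R2 + 1e-9)
  fl <- procrustes_lm(y, ~ ecotype, df, n_perm = 99, seed = 1,
                      phylo = "lambda", tree = ds$tree, lambda = 0)
  expect_equal(fl$table$F, f0$table$F, tolerance = 1e-9)
})

test_that("rank-deficient designs are rejected", {
  df <- data.frame(x = rnorm(10))
  df$x2 <- 2 * df$x
  y <- matrix(rnorm(10), ncol = 1)
  expect_error(procrustes_lm(y, ~ x + x2, df, n_perm = 9), "rank-deficient")
})

test_that("Pillai's trace matches stats::manova and the univariate reduction", {
  set.seed(4)
  n <- 21
  df <- data.frame(x = rnorm(n), g = factor(rep(letters[1:3], n / 3)))
  Y <- cbind(1 + df$x + rnorm(n), rnorm(n), (df$g == "c") + rnorm(n))
  mine <- pillai_manova(Y, ~ x + g, df, n_perm = 99, seed = 1)
  ref <- summary(stats::manova(Y ~ x + g, df), test = "Pillai")
  expect_equal(mine$table$pillai, unname(ref$stats[1:2, "Pillai"]),
               tolerance = 1e-10)

  y1 <- Y[, 1, drop = FALSE]
  uni <- pillai_manova(y1, ~ x + g, df, n_perm = 99, seed = 1)
  a <- anova(lm(y1 ~ x + g, df))
  ss <- a$`Sum Sq`
  expect_equal(uni$table$pillai, c(ss[1] / (ss[1] + ss[3]), ss[2] / (ss[2] + ss[3])),
               tolerance = 1e-12)

  # duplicated response column: same permutation p as univariate
  dup <- pillai_manova(cbind(y1, y1 + rnorm(n, sd = 1e-8)), ~ x + g, df,
                       n_perm = 499, seed = 7)
  uni2 <- pillai_manova(y1, ~ x + g, df, n_perm = 499, seed = 7)
  expect_equal(dup$table$p, uni2$table$p, tolerance = 0.05)

  expect_error(pillai_manova(matrix(rnorm(10 * 9), 10), ~ x,
                             data.frame(x = rnorm(10)), n_perm = 9),
               "fewer variables")
})

test_that("pairwise group tests detect separated means and stay exchangeable", {
  set.seed(6)
  n <- 30
  g <- factor(rep(c("a", "b", "c"), each = 10))
  Y <- matrix(rnorm(n * 4, sd = 0.5), n, 4)
  Y[g == "b", ] <- Y[g == "b", ] + 10  # b far from a and c
  df <- data.frame(ecotype = g)
  fit <- procrustes_lm(Y, ~ ecotype, df, n_perm = 199, seed = 2)
  pw <- pairwise_groups(fit, "ecotype", n_perm = 199, seed = 2)
  ab <- pw[pw$group1 == "a" & pw$group2 == "b", ]
  ac <- pw[pw$group1 == "a" & pw$group2 == "c", ]
  expect_equal(ab$p, 1 / 200)        # saturated shift
  expect_gt(ac$p, 0.05)              # identical distributions
  expect_lt(ac$distance, ab$distance)
})

test_that("pairwise distances agree with exhaustive permutations at n = 6", {
  set.seed(8)
  g <- factor(rep(c("a", "b", "c"), each = 2))
  Y <- matrix(rnorm(12), 6, 2) + 2 * (g == "b")
  df <- data.frame(ecotype = g)
  fit <- procrustes_lm(Y, ~ ecotype, df, n_perm = 99, seed = 1)
  ex <- pairwise_groups(fit, "ecotype", n_perm = "exhaustive")
  sm <- pairwise_groups(fit, "ecotype", n_perm = 9999, seed = 5)
  expect_equal(sm$p, ex$p, tolerance = 0.03)
})

test_that("two-block PLS finds perfect, constructed and rotated covariation", {
  set.seed(12)
  X <- matrix(rnorm(30 * 4), 30, 4)
  self <- two_block_pls(X, X, n_perm = 99, seed = 1)
  expect_equal(self$r_pls, 1, tolerance = 1e-10)

  A <- matrix(rnorm(4 * 3), 4, 3)
  Y <- X %*% A + matrix(rnorm(30 * 3, sd = 0.05), 30, 3)
  link <- two_block_pls(X, Y, n_perm = 199, seed = 1)
  expect_gt(link$r_pls, 0.95)
  expect_lt(link$p, 0.05)

  # r_PLS is invariant to separate rotations of each block
  Q1 <- qr.Q(qr(matrix(rnorm(16), 4, 4)))
  Q2 <- qr.Q(qr(matrix(rnorm(9), 3, 3)))
  rot <- two_block_pls(X %*% Q1, Y %*% Q2, n_perm = 9, seed = 1)
  expect_equal(rot$r_pls, link$r_pls, tolerance = 1e-8)

  expect_error(two_block_pls(X, matrix(1, 30, 2), n_perm = 9), "zero variance")
})

test_that("CVA separates separated clouds and respects the rank bound", {
  set.seed(14)
  X <- rbind(matrix(rnorm(60), 20, 3), matrix(rnorm(60), 20, 3) + 15)
  g <- rep(c("a", "b"), each = 20)
  cv <- cva_jackknife(X, g)
  expect_equal(cv$overall_accuracy, 100)
  expect_equal(ncol(cv$axes), 1L)  # g = 2 -> one canonical axis
  expect_equal(unname(cv$per_group_accuracy), c(100, 100))

  # overall accuracy is the specimen-weighted mean of per-group accuracies
  X2 <- rbind(matrix(rnorm(30), 10, 3), matrix(rnorm(90), 30, 3) + 0.5)
  g2 <- rep(c("a", "b"), c(10, 30))
  cv2 <- cva_jackknife(X2, g2)
  expect_equal(cv2$overall_accuracy,
               sum(cv2$per_group_accuracy * c(10, 30)) / 40)

  expect_warning(cva_jackknife(X, g, retained_dims = 50), "reduced")
  expect_error(cva_jackknife(X, rep("a", 40)), "2 groups")
})

test_that("CVA accuracy shrinks toward chance as separation vanishes", {
  set.seed(16)
  base <- matrix(rnorm(40 * 3), 40, 3)
  g <- rep(c("a", "b"), each = 20)
  acc <- vapply(c(8, 2, 0), function(delta) {
    X <- base + outer(as.numeric(g == "b") * delta, rep(1, 3))
    cva_jackknife(X, g)$overall_accuracy
  }, numeric(1))
  expect_true(all(diff(acc) <= 0))
})

test_that("shape PCA conserves variance and projects ancestors sensibly", {
  set.seed(18)
  # rank-1 data: a single line in shape space
  t_par <- rnorm(10)
  M <- outer(t_par, rnorm(6))
  pca_line <- shape_pca(M)
  expect_equal(pca_line$percent_variance[1], 100, tolerance = 1e-8)

  M2 <- matrix(rnorm(10 * 6), 10, 6)
  pca <- shape_pca(M2)
  expect_equal(sum(pca$eigenvalues), sum(diag(cov(M2))), tolerance = 1e-10)

  # star tree: root reconstruction equals the tip mean, hence score 0
  st <- ape::stree(8, "star")
  st$edge.length <- rep(1, 8)
  st$tip.label <- paste0("t", 1:8)
  M3 <- matrix(rnorm(8 * 6), 8, 6, dimnames = list(st$tip.label, NULL))
  pp <- shape_pca(M3, tree = st)
  expect_lt(max(abs(pp$node_scores[1, ])), 1e-10)
  expect_error(shape_pca(M3[1, , drop = FALSE]), "at least 2")
})
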