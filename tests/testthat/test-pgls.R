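test_that("phylo covariance satisfies the lambda identity and limits", {
  tr <- simulate_phylogeny(10, seed = 1)
  C1 <- phylo_covariance(tr, 1)
  C0 <- phylo_covariance(tr, 0)
  expect_equal(C0, diag(diag(C1)), ignore_attr = TRUE)
  lam <- 0.37
  expect_equal(phylo_covariance(tr, lam), lam * C1 + (1 - lam) * diag(diag(C1)),
               ignore_attr = TRUE)
  # two sister tips at depth T diverging at T - t share T - t
  two <- ape::read.tree(text = "(a:2,b:2);")
  expect_equal(phylo_covariance(two, 1)["a", "b"], 0)
  sis <- ape::read.tree(text = "((a:1,b:1):3,c:4);")
  expect_equal(phylo_covariance(sis, 1)["a", "b"], 3)
  expect_error(phylo_covariance(tr, 1.2), "lambda")
})

test_that("PGLS reduces to OLS at lambda 0 and to contrasts at lambda 1", {
  ds <- small_dataset()
  df <- ds$specimens
  f0 <- pgls_fit(de ~ lnsize, df, ds$tree, lambda = 0)
  ols <- lm(de ~ lnsize, df)
  expect_equal(unname(f0$coefficients), unname(coef(ols)), tolerance = 1e-10)

  f1 <- pgls_fit(de ~ lnsize, df, ds$tree, lambda = 1)
  px <- ape::pic(df[ds$tree$tip.label, "lnsize"], ds$tree)
  py <- ape::pic(df[ds$tree$tip.label, "de"], ds$tree)
  expect_equal(unname(f1$coefficients[2]), sum(px * py) / sum(px^2),
               tolerance = 1e-6)
})

test_that("star phylogenies collapse to OLS with unidentifiable lambda", {
  st <- ape::stree(12, "star")
  st$edge.length <- rep(1, 12)
  st$tip.label <- paste0("t", 1:12)
  set.seed(3)
  df <- data.frame(x = rnorm(12), row.names = st$tip.label)
  df$y <- 1 + 2 * df$x + rnorm(12)
  fit <- pgls_fit(y ~ x, df, st, lambda = "ML")
  expect_false(fit$lambda_identifiable)
  expect_equal(unname(fit$coefficients), unname(coef(lm(y ~ x, df))),
               tolerance = 1e-10)
})

test_that("jointly estimated lambda matches the nlme profile-ML oracle", {
  skip_if_not_installed("nlme")
  set.seed(42)
  tr <- simulate_phylogeny(40, seed = 11)
  C <- ape::vcv(tr)
  x <- drop(crossprod(chol(0.3 * C), rnorm(40)))
  Cl <- 0.6 * C; diag(Cl) <- diag(C)
  y <- 1 + 0.5 * x + drop(crossprod(chol(0.2 * Cl), rnorm(40)))
  d <- data.frame(y = y, x = x, sp = tr$tip.label, row.names = tr$tip.label)
  mine <- pgls_fit(y ~ x, d, tr)
  ref <- nlme::gls(y ~ x, data = d, method = "ML",
                   correlation = ape::corPagel(0.5, tr, form = ~sp))
  expect_equal(mine$lambda, unname(ref$modelStruct$corStruct[1]), tolerance = 1e-4)
  expect_equal(unname(mine$coefficients), unname(coef(ref)), tolerance = 1e-6)
  expect_equal(mine$logLik, as.numeric(logLik(ref)), tolerance = 1e-6)
})

test_that("profile likelihood at the estimate dominates fixed lambdas", {
  ds <- small_dataset()
  df <- ds$specimens
  for (tr_name in c("cg", "de", "css")) {
    fml <- as.formula(paste(tr_name, "~ lnsize * ecotype"))
    fit <- pgls_fit(fml, df, ds$tree, lambda = "ML")
    for (lam in c(0, 0.5, 1)) {
      expect_gte(fit$logLik + 1e-8,
                 pgls_fit(fml, df, ds$tree, lambda = lam)$logLik)
    }
  }
})

test_that("model-set comparison normalizes weights and flags support", {
  ds <- small_dataset()
  cmp <- fit_model_set(ds$specimens, "de", ds$tree)
  expect_equal(sum(cmp$table$AICw), 1, tolerance = 1e-12)
  expect_equal(min(cmp$table$dAIC), 0)
  expect_true(all(cmp$table$supported == (cmp$table$dAIC < 2)))
  expect_equal(nrow(cmp$table), 5L)
  # two models dAIC {0, 2} have weights 1/(1+e^-1) and its complement
  w <- exp(-c(0, 2) / 2); w <- w / sum(w)
  expect_equal(w, c(0.7310586, 0.2689414), tolerance = 1e-6)
})

test_that("parametric bootstrap is deterministic and collapses when noise-free", {
  ds <- small_dataset()
  df <- ds$specimens
  fit <- pgls_fit(de ~ lnsize * ecotype, df, ds$tree)
  b1 <- bootstrap_coefficients(fit, 100, seed = 5)
  b2 <- bootstrap_coefficients(fit, 100, seed = 5)
  expect_identical(b1$coefficients, b2$coefficients)
  expect_equal(nrow(b1$coefficients), 100L)

  # response exactly on the regression plane: replicates equal beta-hat
  df2 <- df
  df2$exact <- 1 + 2 * df2$lnsize
  fit0 <- pgls_fit(exact ~ lnsize, df2, ds$tree, lambda = 0)
  b0 <- bootstrap_coefficients(fit0, 50, seed = 1)
  expect_lt(max(abs(sweep(b0$coefficients, 2, fit0$coefficients))), 1e-6)
})

test_that("pairwise bootstrap CIs are antisymmetric and saturate", {
  ds <- small_dataset()
  df <- ds$specimens
  df$shifted <- df$de + 50 * (df$ecotype == levels(df$ecotype)[1])
  fit <- pgls_fit(shifted ~ lnsize * ecotype, df, ds$tree)
  boot <- bootstrap_coefficients(fit, 200, seed = 9)
  pw <- pairwise_ci(boot, "means")
  first <- levels(df$ecotype)[1]
  sat <- pw[pw$group1 == first, ]
  expect_true(all(sat$significant))
  # shift dominates the intrinsic ecotype differences in DE
  expect_true(all(sat$observed > 30))
  # antisymmetry: recompute with reversed pair by hand
  L <- osteomorph:::group_combination(fit, "means")
  obs <- drop(L %*% fit$coefficients)
  expect_equal(unname(obs[1] - obs[2]), -unname(obs[2] - obs[1]))
  expect_error(pairwise_ci(boot, "slopes", ecotype = "nope"), "does not contain")
})

test_that("allometry verdicts follow the CI sign pattern", {
  expect_equal(classify_allometry(0.08, 0.47)$verdict, "positive")
  expect_equal(classify_allometry(-3.88, -0.29)$verdict, "negative")
  expect_equal(classify_allometry(-2.11, 0.89)$verdict, "isometric")
  expect_equal(classify_allometry(0, 0.5)$verdict, "isometric")  # boundary
  expect_error(classify_allometry(1, -1), "reversed")
  expect_error(classify_allometry(NA, 1), "finite")
})

test_that("slope CIs cover the generating slopes in a quick recovery run", {
  ds <- small_dataset()
  df <- ds$specimens
  fit <- pgls_fit(de ~ lnsize * ecotype, df, ds$tree)
  boot <- bootstrap_coefficients(fit, 300, seed = 13)
  sc <- slope_cis(boot)
  truth <- ds$ground_truth$trait_params$de$beta1
  hits <- vapply(seq_len(4), function(e) {
    row <- sc[sc$group == levels(df$ecotype)[e], ]
    truth[e] >= row$lower && truth[e] <= row$upper
  }, logical(1))
  expect_gte(sum(hits), 3L)
  expect_equal(nrow(sc), 5L)  # 4 ecotypes + overall mean slope
  expect_true(all(sc$verdict %in% c("positive", "negative", "isometric")))
})

test_that("phylogenetic ANOVA reduces to classical R2 at lambda 0 and saturates", {
  ds <- small_dataset()
  df <- ds$specimens
  f0 <- pgls_fit(de ~ ecotype, df, ds$tree, lambda = 0)
  ols <- summary(lm(de ~ ecotype, df))
  expect_equal(f0$R2, ols$r.squared, tolerance = 1e-10)

  y_big <- setNames(10 * as.integer(df$ecotype) + rnorm(nrow(df), sd = 0.01),
                    rownames(df))
  fit <- phylo_anova(y_big, df$ecotype, ds$tree)
  expect_gt(fit$R2, 0.9)
  expect_error(phylo_anova(y_big, rep("a", nrow(df)), ds$tree), "2 groups")
})

test_that("phylogenetic paired t-test behaves at the degenerate and saturated ends", {
  ds <- small_dataset()
  a <- setNames(ds$specimens$cg, rownames(ds$specimens))
  same <- phylo_paired_ttest(a, a, ds$tree)
  expect_true(same$degenerate)
  expect_equal(same$mean_diff, 0)

  set.seed(7)
  b <- a + 5 + rnorm(length(a), sd = 0.05)
  shifted <- phylo_paired_ttest(b, a, ds$tree)
  expect_lt(shifted$p, 0.001)
  expect_gt(shifted$mean_diff, 4)

  skip_if_not_installed("phytools")
  d1 <- a + 0.3 + rnorm(length(a), sd = 0.2)
  ours <- phylo_paired_ttest(d1, a, ds$tree)
  ref <- phytools::phyl.pairedttest(ds$tree, d1, a)
  expect_equal(ours$mean_diff, unname(ref$dbar), tolerance = 0.05)
})
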