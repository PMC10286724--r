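# Univariate phylogenetic generalized least squares with jointly estimated
# Pagel's lambda, model comparison by AICc weights, parametric bootstrap of
# coefficients, and derived allometry calls.

#' Phylogenetic covariance matrix under Pagel's lambda
#'
#' Brownian-motion covariance (shared root-to-MRCA branch length) with
#' off-diagonal entries multiplied by `lambda`; diagonals (root-to-tip
#' lengths) are unchanged. Satisfies
#' `C(lambda) = lambda * C(1) + (1 - lambda) * diag(C(1))`.
#'
#' @param tree `ape::phylo` with branch lengths.
#' @param lambda Pagel's lambda in `[0, 1]`.
#' @return Symmetric covariance matrix with tip-label dimnames.
#' @export
phylo_covariance <- function(tree, lambda = 1) {
  if (lambda < 0 || lambda > 1) stopf("lambda must be in [0, 1]")
  C <- ape::vcv(tree)
  Cl <- lambda * C
  diag(Cl) <- diag(C)
  Cl
}

# Precompute the eigen-decomposition machinery for repeated lambda fits.
# On ultrametric trees C(lambda) shares eigenvectors for every lambda
# (C(lambda) = V diag(lambda*d + (1-lambda)*T) V'), so each likelihood
# evaluation is a cheap weighted least squares in the rotated basis.
pgls_prep <- function(tree, tips) {
  C <- ape::vcv(tree)
  miss <- setdiff(tips, rownames(C))
  if (length(miss)) stopf("tree is missing tips: %s", paste(miss, collapse = ", "))
  C <- C[tips, tips]
  depths <- diag(C)
  ultra <- diff(range(depths)) < 1e-8 * max(depths)
  if (ultra) {
    E <- eigen(C, symmetric = TRUE)
    list(ultra = TRUE, V = E$vectors, d = E$values, depth = depths[1], C = C)
  } else {
    list(ultra = FALSE, C = C)
  }
}

# ML fit for a fixed lambda on the (rotated, for ultrametric trees) problem.
pgls_eval <- function(prep, ytil, Xtil, lambda) {
  n <- length(ytil)
  if (prep$ultra) {
    w <- lambda * prep$d + (1 - lambda) * prep$depth
    sw <- 1 / sqrt(w)
    fit <- stats::lm.fit(Xtil * sw, ytil * sw)
    q <- sum(fit$residuals^2)
    logdet <- sum(log(w))
    beta <- fit$coefficients
    XtCiX <- crossprod(Xtil * sw)
  } else {
    Cl <- lambda * prep$C
    diag(Cl) <- diag(prep$C)
    R <- chol(Cl)
    yw <- backsolve(R, ytil, transpose = TRUE)
    Xw <- backsolve(R, Xtil, transpose = TRUE)
    fit <- stats::lm.fit(Xw, yw)
    q <- sum(fit$residuals^2)
    logdet <- 2 * sum(log(diag(R)))
    beta <- fit$coefficients
    XtCiX <- crossprod(Xw)
  }
  sigma2 <- q / n
  ll <- -0.5 * (n * log(2 * pi * sigma2) + logdet + n)
  list(beta = beta, sigma2 = sigma2, q = q, logLik = ll, XtCiX = XtCiX)
}

# Profile-likelihood lambda: 11-point grid scan then bounded optimization in
# the bracketing interval; ties (flat profiles) resolve toward smaller lambda.
pgls_profile_lambda <- function(prep, ytil, Xtil) {
  grid <- seq(0, 1, length.out = 11)
  ll <- vapply(grid, function(l) pgls_eval(prep, ytil, Xtil, l)$logLik, numeric(1))
  identifiable <- (max(ll) - min(ll)) > 1e-8
  if (!identifiable) return(list(lambda = 0, identifiable = FALSE))
  b <- which.max(ll)
  lo <- grid[max(b - 1L, 1L)]
  hi <- grid[min(b + 1L, length(grid))]
  opt <- stats::optimize(function(l) pgls_eval(prep, ytil, Xtil, l)$logLik,
                         interval = c(lo, hi), maximum = TRUE, tol = 1e-8)
  if (opt$objective >= ll[b] + 1e-12) {
    list(lambda = opt$maximum, identifiable = TRUE)
  } else {
    list(lambda = grid[b], identifiable = TRUE)
  }
}

#' Fit a phylogenetic generalized least squares model
#'
#' GLS regression whose error covariance is the lambda-scaled Brownian
#' covariance of the tree. For fixed lambda,
#' `beta = (X' C^-1 X)^-1 X' C^-1 y`, `sigma2 = e' C^-1 e / n` (ML), and
#' `logLik = -1/2 (n log(2 pi sigma2) + log|C| + n)`. With `lambda = "ML"`
#' the profile likelihood is maximized over `[0, 1]`. AICc counts
#' `k = #beta + 2` parameters (sigma2 and lambda); R2 is computed against
#' the GLS intercept-only fit at the same lambda.
#'
#' @param formula model formula; variables are columns of `data`.
#' @param data data.frame whose rownames are tip labels.
#' @param tree `ape::phylo` containing all data rows as tips.
#' @param lambda `"ML"` or a fixed value in `[0, 1]`.
#' @return An object of class `pgls_fit`.
#' @export
pgls_fit <- function(formula, data, tree, lambda = "ML") {
  mf <- stats::model.frame(formula, data)
  y <- stats::model.response(mf)
  X <- stats::model.matrix(attr(mf, "terms"), mf)
  tips <- rownames(data)
  if (is.null(tips)) stopf("data must have tip labels as rownames")
  n <- length(y)
  if (n < ncol(X) + 2L) stopf("need at least 2 more tips than design columns")
  if (any(!is.finite(y))) stopf("non-finite response values")

  prep <- pgls_prep(tree, tips)
  if (prep$ultra) {
    ytil <- drop(crossprod(prep$V, y))
    Xtil <- crossprod(prep$V, X)
  } else {
    ytil <- y
    Xtil <- X
  }

  if (identical(lambda, "ML")) {
    prof <- pgls_profile_lambda(prep, ytil, Xtil)
    lam <- prof$lambda
    identifiable <- prof$identifiable
  } else {
    if (!is.numeric(lambda) || lambda < 0 || lambda > 1) {
      stopf("lambda must be 'ML' or a number in [0, 1]")
    }
    lam <- lambda
    identifiable <- TRUE
  }

  fit <- pgls_eval(prep, ytil, Xtil, lam)
  if (any(!is.finite(fit$beta))) stopf("singular design (X' C^-1 X not invertible)")
  k <- ncol(X) + 2L
  aicc <- -2 * fit$logLik + 2 * k + 2 * k * (k + 1) / max(n - k - 1, 1e-8)
  # GLS R2 against the intercept-only fit at the same lambda
  ones_til <- if (prep$ultra) crossprod(prep$V, matrix(1, n, 1)) else matrix(1, n, 1)
  null_fit <- pgls_eval(prep, ytil, ones_til, lam)
  r2 <- max(0, min(1, 1 - fit$q / null_fit$q))
  sigma2_unb <- fit$q / (n - ncol(X))
  vcov_beta <- sigma2_unb * solve(fit$XtCiX)
  fitted <- drop(X %*% fit$beta)

  structure(
    list(
      coefficients = fit$beta, sigma2 = fit$sigma2, lambda = lam,
      lambda_identifiable = identifiable, logLik = fit$logLik, AICc = aicc,
      R2 = r2, fitted = stats::setNames(fitted, tips),
      residuals = stats::setNames(y - fitted, tips),
      se = sqrt(diag(vcov_beta)), vcov = vcov_beta,
      n = n, k = k, df.residual = n - ncol(X),
      formula = formula, data = data, tree = tree,
      prep = prep, X = X, Xtil = Xtil, y = y
    ),
    class = "pgls_fit"
  )
}

#' @export
print.pgls_fit <- function(x, ...) {
  cat(sprintf("PGLS: %s  (n = %d, lambda = %.3f%s)\n", deparse(x$formula), x$n,
              x$lambda, if (x$lambda_identifiable) "" else ", unidentifiable"))
  print(round(cbind(estimate = x$coefficients, se = x$se), 4))
  cat(sprintf("sigma2 = %.4g, logLik = %.3f, AICc = %.2f, R2 = %.3f\n",
              x$sigma2, x$logLik, x$AICc, x$R2))
  invisible(x)
}

#' Fit the five-design model set and compare by AICc weights
#'
#' Fits null, size, ecotype, size + ecotype, and size x ecotype designs with
#' jointly estimated lambda, then ranks them with
#' `AICw = exp(-dAIC/2) / sum(exp(-dAIC/2))`; models with `dAIC < 2` are
#' flagged as supported.
#'
#' @param data data.frame (rownames = tips) with the trait, size and ecotype
#'   columns.
#' @param trait,size,ecotype column names; defaults `"lnsize"`/`"ecotype"`.
#' @param tree `ape::phylo`.
#' @return A list of class `model_comparison`: `table` (model, R2, lambda,
#'   AICc, dAIC, AICw, supported) and `fits`.
#' @export
fit_model_set <- function(data, trait, tree, size = "lnsize",
                          ecotype = "ecotype") {
  eco <- factor(data[[ecotype]])
  designs <- list(
    null = sprintf("%s ~ 1", trait),
    size = sprintf("%s ~ %s", trait, size),
    ecotype = sprintf("%s ~ %s", trait, ecotype),
    `size+ecotype` = sprintf("%s ~ %s + %s", trait, size, ecotype),
    `size*ecotype` = sprintf("%s ~ %s * %s", trait, size, ecotype)
  )
  if (any(table(eco) < 2L)) {
    warnf("an ecotype has fewer than 2 tips; skipping the interaction model")
    designs[["size*ecotype"]] <- NULL
  }
  fits <- lapply(designs, function(f) {
    pgls_fit(stats::as.formula(f), data, tree, lambda = "ML")
  })
  aicc <- vapply(fits, `[[`, numeric(1), "AICc")
  delta <- aicc - min(aicc)
  w <- exp(-delta / 2)
  w <- w / sum(w)
  table <- data.frame(
    model = names(fits),
    R2 = vapply(fits, `[[`, numeric(1), "R2"),
    lambda = vapply(fits, `[[`, numeric(1), "lambda"),
    AICc = aicc, dAIC = delta, AICw = w, supported = delta < 2,
    row.names = NULL
  )
  structure(list(table = table[order(table$dAIC), ], fits = fits),
            class = "model_comparison")
}

#' @export
print.model_comparison <- function(x, ...) {
  print(x$table, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Parametric bootstrap of PGLS coefficients
#'
#' Simulates `y* = X beta_hat + e*` with `e* ~ N(0, sigma2_hat C(lambda_hat))`
#' and refits the model (re-estimating lambda) for each replicate. Tips are
#' not exchangeable under phylogenetic covariance, so replicates are drawn
#' from the fitted model rather than by case resampling. Non-converged
#' replicates are redrawn up to a retry cap and counted.
#'
#' @param fit a [pgls_fit()].
#' @param n_boot number of replicates.
#' @param seed RNG seed.
#' @return An object of class `bootstrap_ensemble`: `coefficients`
#'   (`n_boot x p` matrix), `lambda` (replicate estimates), `failures`,
#'   `seed`, `fit`.
#' @export
bootstrap_coefficients <- function(fit, n_boot = 1000L, seed = NULL) {
  stopifnot(inherits(fit, "pgls_fit"))
  prep <- fit$prep
  n <- fit$n
  X <- fit$X
  Xtil <- fit$Xtil
  mu_til <- drop(Xtil %*% fit$coefficients)
  p <- ncol(X)
  # simulate from the df-corrected residual variance: the ML estimate is
  # biased low and produces CIs that systematically undercover
  sigma2_sim <- fit$sigma2 * n / fit$df.residual

  if (prep$ultra) {
    w <- fit$lambda * prep$d + (1 - fit$lambda) * prep$depth
    sdev <- sqrt(sigma2_sim * w)
  } else {
    Cl <- fit$lambda * prep$C
    diag(Cl) <- diag(prep$C)
    Lt <- chol(sigma2_sim * Cl)
  }

  out <- matrix(NA_real_, n_boot, p, dimnames = list(NULL, names(fit$coefficients)))
  lambdas <- numeric(n_boot)
  failures <- 0L
  with_seed(seed, {
    i <- 1L
    tries <- 0L
    while (i <= n_boot && tries < 10L * n_boot) {
      tries <- tries + 1L
      res <- tryCatch({
        if (prep$ultra) {
          ystar <- mu_til + stats::rnorm(n, sd = sdev)
        } else {
          ystar <- drop(X %*% fit$coefficients) + drop(crossprod(Lt, stats::rnorm(n)))
        }
        prof <- pgls_profile_lambda(prep, ystar, Xtil)
        ev <- pgls_eval(prep, ystar, Xtil, prof$lambda)
        list(beta = ev$beta, lambda = prof$lambda)
      }, error = function(e) NULL)
      if (is.null(res) || any(!is.finite(res$beta))) {
        failures <- failures + 1L
        next
      }
      out[i, ] <- res$beta
      lambdas[i] <- res$lambda
      i <- i + 1L
    }
    if (i <= n_boot) stopf("bootstrap failed to converge after retries")
  })
  structure(
    list(coefficients = out, lambda = lambdas, failures = failures,
         n_boot = n_boot, seed = seed, fit = fit),
    class = "bootstrap_ensemble"
  )
}

# evaluate per-group least-squares means (at a fixed size) and per-group
# slopes as linear combinations of model coefficients
group_combination <- function(fit, quantity = c("means", "slopes"),
                              size = "lnsize", ecotype = "ecotype",
                              at_size = NULL) {
  quantity <- match.arg(quantity)
  vars <- all.vars(fit$formula)
  has_size <- size %in% vars
  has_eco <- ecotype %in% vars
  mt <- stats::delete.response(stats::terms(fit$formula))
  data <- fit$data
  if (has_eco) {
    levs <- levels(factor(data[[ecotype]]))
  } else {
    levs <- "all"
  }
  if (quantity == "slopes" && !has_size) stopf("model has no size term")
  if (quantity == "means" && !has_eco && is.null(at_size)) at_size <- NA

  newdata <- data[rep(1L, length(levs)), , drop = FALSE]
  if (has_eco) newdata[[ecotype]] <- factor(levs, levels = levs)
  if (has_size) {
    x0 <- at_size %||% mean(data[[size]])
    newdata[[size]] <- x0
  }
  L0 <- stats::model.matrix(mt, newdata)
  if (quantity == "means") {
    rownames(L0) <- levs
    return(L0)
  }
  newdata[[size]] <- (if (has_size) (at_size %||% mean(data[[size]])) else 0) + 1
  L1 <- stats::model.matrix(mt, newdata)
  L <- L1 - L0
  rownames(L) <- levs
  L
}

#' Pairwise bootstrap confidence intervals for group means or slopes
#'
#' For each unordered ecotype pair, the observed difference in least-squares
#' means (covariates at the grand-mean size) or in per-group scaling slopes,
#' with a 95% percentile interval from the bootstrap replicates; the pair is
#' flagged significant when the interval excludes zero.
#'
#' @param ensemble a [bootstrap_coefficients()] ensemble.
#' @param quantity `"means"` or `"slopes"` (slopes need the interaction
#'   model).
#' @param size,ecotype variable names in the fitted model.
#' @return A data.frame of pairs with `observed`, `lower`, `upper`,
#'   `significant`. Differences are antisymmetric:
#'   `difference(i, j) = -difference(j, i)`.
#' @export
pairwise_ci <- function(ensemble, quantity = c("means", "slopes"),
                        size = "lnsize", ecotype = "ecotype") {
  stopifnot(inherits(ensemble, "bootstrap_ensemble"))
  quantity <- match.arg(quantity)
  fit <- ensemble$fit
  if (!ecotype %in% all.vars(fit$formula)) {
    stopf("model does not contain '%s'", ecotype)
  }
  if (quantity == "slopes" &&
      !any(grepl(":", attr(stats::terms(fit$formula), "term.labels")))) {
    stopf("per-group slopes need the size x ecotype interaction model")
  }
  L <- group_combination(fit, quantity, size, ecotype)
  obs <- drop(L %*% fit$coefficients)
  reps <- ensemble$coefficients %*% t(L)
  levs <- rownames(L)
  pairs <- utils::combn(seq_along(levs), 2)
  res <- lapply(seq_len(ncol(pairs)), function(j) {
    a <- pairs[1, j]; b <- pairs[2, j]
    d_obs <- obs[a] - obs[b]
    d_rep <- reps[, a] - reps[, b]
    ci <- stats::quantile(d_rep, c(0.025, 0.975), names = FALSE)
    data.frame(group1 = levs[a], group2 = levs[b], observed = d_obs,
               lower = ci[1], upper = ci[2],
               significant = ci[1] > 0 | ci[2] < 0)
  })
  do.call(rbind, res)
}

#' Bootstrap confidence intervals for scaling slopes
#'
#' Per-ecotype slopes (interaction model) and/or the mean slope across
#' ecotypes, with 95% percentile intervals and an allometry verdict per row
#' via [classify_allometry()]. For models with a single common slope the
#' single row `all` is returned.
#'
#' @param ensemble a [bootstrap_coefficients()] ensemble from a model
#'   containing the size term.
#' @param size,ecotype variable names in the fitted model.
#' @return A data.frame with `group`, `slope`, `lower`, `upper`, `verdict`.
#' @export
slope_cis <- function(ensemble, size = "lnsize", ecotype = "ecotype") {
  stopifnot(inherits(ensemble, "bootstrap_ensemble"))
  fit <- ensemble$fit
  L <- group_combination(fit, "slopes", size, ecotype)
  obs <- drop(L %*% fit$coefficients)
  reps <- ensemble$coefficients %*% t(L)
  levs <- rownames(L)
  rows <- lapply(seq_along(levs), function(a) {
    ci <- stats::quantile(reps[, a], c(0.025, 0.975), names = FALSE)
    data.frame(group = levs[a], slope = obs[a], lower = ci[1], upper = ci[2])
  })
  out <- do.call(rbind, rows)
  if (length(levs) > 1L) {
    mean_rep <- rowMeans(reps)
    ci <- stats::quantile(mean_rep, c(0.025, 0.975), names = FALSE)
    out <- rbind(out, data.frame(group = "all", slope = mean(obs),
                                 lower = ci[1], upper = ci[2]))
  }
  out$verdict <- vapply(seq_len(nrow(out)), function(i) {
    classify_allometry(out$lower[i], out$upper[i])$verdict
  }, character(1))
  out
}

#' Classify allometry from a slope confidence interval
#'
#' Structure traits are dimensionless, so isometry corresponds to a zero
#' scaling slope: an interval entirely above zero is positive allometry,
#' entirely below zero negative allometry, and an interval including zero is
#' isometric.
#'
#' @param lower,upper confidence-interval bounds.
#' @return A list of class `allometry_call` with `verdict`
#'   (`"positive"`/`"negative"`/`"isometric"`) and the bounds.
#' @export
classify_allometry <- function(lower, upper) {
  if (!is.finite(lower) || !is.finite(upper)) stopf("CI bounds must be finite")
  if (lower > upper) stopf("reversed CI bounds (%g > %g)", lower, upper)
  verdict <- if (lower > 0) "positive" else if (upper < 0) "negative" else "isometric"
  structure(list(verdict = verdict, lower = lower, upper = upper),
            class = "allometry_call")
}

#' @export
print.allometry_call <- function(x, ...) {
  cat(sprintf("[%g, %g] -> %s\n", x$lower, x$upper, x$verdict))
  invisible(x)
}

#' Phylogenetic analysis of variance
#'
#' PGLS with a group-indicator design and jointly estimated lambda; the
#' reported R2 is that of the group term against the intercept-only GLS fit.
#'
#' @param y named numeric vector (names = tips) or column name in `data`.
#' @param groups factor of group labels per tip.
#' @param tree `ape::phylo`.
#' @return A [pgls_fit()] (its `R2` and `lambda` are the headline outputs).
#' @export
phylo_anova <- function(y, groups, tree) {
  g <- factor(groups)
  if (nlevels(g) < 2L) stopf("need at least 2 groups")
  data <- data.frame(y = as.numeric(y), group = g,
                     row.names = names(y) %||% names(groups))
  pgls_fit(y ~ group, data, tree, lambda = "ML")
}

#' Phylogenetic paired t-test
#'
#' Tests whether two traits measured on the same tips differ on average,
#' accounting for phylogeny: the tip-wise difference is modeled by an
#' intercept-only PGLS with jointly estimated lambda, and
#' `t = intercept / SE` is referred to a t distribution with `n - 1` df.
#' A single lambda is estimated for the difference vector.
#'
#' @param trait_a,trait_b named numeric vectors on identical tips.
#' @param tree `ape::phylo`.
#' @return A list of class `phylo_ttest`: `mean_diff` (phylogenetic mean
#'   difference), `se`, `t`, `df`, `p`, `lambda`, `degenerate`.
#' @export
phylo_paired_ttest <- function(trait_a, trait_b, tree) {
  if (is.null(names(trait_a)) || is.null(names(trait_b))) {
    stopf("traits must be named by tip")
  }
  if (!setequal(names(trait_a), names(trait_b))) {
    stopf("traits must be measured on identical tips")
  }
  d <- trait_a - trait_b[names(trait_a)]
  n <- length(d)
  if (stats::sd(d) < 1e-12) {
    return(structure(
      list(mean_diff = mean(d), se = 0, t = NA_real_, df = n - 1L,
           p = NA_real_, lambda = NA_real_, degenerate = TRUE),
      class = "phylo_ttest"
    ))
  }
  data <- data.frame(d = d, row.names = names(d))
  fit <- pgls_fit(d ~ 1, data, tree, lambda = "ML")
  se <- fit$se[1]  # GLS SE with the unbiased variance (df = n - 1)
  tval <- fit$coefficients[1] / se
  p <- 2 * stats::pt(-abs(tval), df = n - 1)
  structure(
    list(mean_diff = unname(fit$coefficients[1]), se = unname(se),
         t = unname(tval), df = n - 1L, p = unname(p), lambda = fit$lambda,
         degenerate = FALSE),
    class = "phylo_ttest"
  )
}

#' @export
print.phylo_ttest <- function(x, ...) {
  if (x$degenerate) {
    cat("Phylogenetic paired t-test: degenerate (constant difference)\n")
  } else {
    cat(sprintf(
      "Phylogenetic paired t-test: mean diff = %.4g (SE %.4g), t(%d) = %.3f, p = %.4g, lambda = %.3f\n",
      x$mean_diff, x$se, x$df, x$t, x$p, x$lambda))
  }
  invisible(x)
}
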