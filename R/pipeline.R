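# End-to-end orchestration: (synthesize or load) -> structure traits ->
# GPA/centroid size -> size and shape models -> per-trait PGLS competition
# with bootstrap allometry calls -> PLS -> CVA -> paired t-tests -> report.

#' Build a pipeline configuration
#'
#' With no input paths the pipeline runs on a synthetic dataset generated
#' from `params`. Every stochastic stage draws its stream from `seed` through
#' a stage-scoped substream, so adding or removing a stage never perturbs the
#' randomness of the others.
#'
#' @param seed master RNG seed (mandatory).
#' @param params an [evol_params()] for synthetic runs.
#' @param inputs optional list of paths for user data: `tree` (Newick),
#'   `landmarks` (CSV), `specimens` (CSV with specimen, ecotype), `volumes`
#'   (named character vector of TIFF paths, optionally nested per bone).
#' @param stages character vector of stages to run, any of `"structure"`,
#'   `"gpa"`, `"shape_models"`, `"pgls"`, `"pls"`, `"cva"`, `"ttest"`.
#' @param n_perm permutations for RRPP/Pillai/PLS tests.
#' @param n_boot bootstrap replicates for coefficient CIs.
#' @param fraction included fraction of functional length, default 0.40.
#' @param spacing_rel voxel spacing for synthetic bones as a fraction of
#'   `b_mid` (default 1/6; must be <= 1/5).
#' @param out optional output directory; when given, [make_report()] is
#'   called on the result.
#' @return A list of class `run_config`.
#' @export
run_config <- function(seed, params = evol_params(seed = seed), inputs = NULL,
                       stages = c("structure", "gpa", "shape_models", "pgls",
                                  "pls", "cva", "ttest"),
                       n_perm = 999L, n_boot = 500L, fraction = 0.40,
                       spacing_rel = 1 / 6, out = NULL) {
  if (missing(seed) || is.null(seed)) stopf("seed is mandatory")
  if (fraction <= 0 || fraction >= 1) stopf("fraction must be in (0, 1)")
  if (!is.null(inputs)) {
    for (nm in c("tree", "landmarks", "specimens")) {
      if (!is.null(inputs[[nm]]) && !file.exists(inputs[[nm]])) {
        stopf("input path does not exist: %s", inputs[[nm]])
      }
    }
  }
  structure(
    list(seed = as.integer(seed), params = params, inputs = inputs,
         stages = stages, n_perm = n_perm, n_boot = n_boot,
         fraction = fraction, spacing_rel = spacing_rel, out = out),
    class = "run_config"
  )
}

#' Cross-check the consistency of pipeline inputs
#'
#' Compares tree tips, specimen table and landmark/volume specimen ids,
#' reporting orphans in both directions, duplicated ids (fatal), and
#' ecotypes with fewer than 2 tips (the interaction model needs >= 2 per
#' ecotype). Always returns a report rather than erroring.
#'
#' @param tree `ape::phylo` or NULL.
#' @param specimens data.frame with `specimen` and `ecotype` columns, or NULL.
#' @param landmark_ids,volume_ids character vectors of specimen ids, or NULL.
#' @return A data.frame with columns `level` (`"fatal"`/`"warning"`) and
#'   `message`; zero rows when everything is consistent.
#' @export
validate_inputs <- function(tree = NULL, specimens = NULL,
                            landmark_ids = NULL, volume_ids = NULL) {
  problems <- list()
  add <- function(level, msg) {
    problems[[length(problems) + 1L]] <<- data.frame(level = level, message = msg)
  }
  ids <- if (!is.null(specimens)) as.character(specimens$specimen) else NULL
  if (!is.null(ids) && anyDuplicated(ids)) {
    add("fatal", sprintf("duplicated specimen id(s): %s",
                         paste(unique(ids[duplicated(ids)]), collapse = ", ")))
  }
  cross <- function(a, b, what_a, what_b) {
    for (x in setdiff(a, b)) add("warning", sprintf("%s '%s' has no %s", what_a, x, what_b))
  }
  if (!is.null(tree) && !is.null(ids)) {
    cross(tree$tip.label, ids, "tree tip", "specimen row")
    cross(ids, tree$tip.label, "specimen", "tree tip")
  }
  if (!is.null(landmark_ids) && !is.null(ids)) {
    cross(ids, landmark_ids, "specimen", "landmark set")
    cross(landmark_ids, ids, "landmark set", "specimen row")
  }
  if (!is.null(volume_ids) && !is.null(ids)) {
    cross(ids, volume_ids, "specimen", "volume")
    cross(volume_ids, ids, "volume", "specimen row")
  }
  if (!is.null(specimens) && "ecotype" %in% names(specimens)) {
    tab <- table(specimens$ecotype)
    for (e in names(tab)[tab < 2L]) {
      add("warning", sprintf("ecotype '%s' has < 2 tips; interaction model unavailable", e))
    }
  }
  if (!length(problems)) {
    data.frame(level = character(0), message = character(0))
  } else {
    do.call(rbind, problems)
  }
}

# run one stage, isolating failures into the log
run_stage <- function(log_env, name, expr) {
  t0 <- proc.time()[["elapsed"]]
  res <- tryCatch(expr, error = function(e) {
    structure(list(message = conditionMessage(e)), class = "stage_error")
  })
  status <- if (inherits(res, "stage_error")) paste0("failed: ", res$message) else "ok"
  log_env$log[[length(log_env$log) + 1L]] <- data.frame(
    stage = name, status = status,
    seconds = round(proc.time()[["elapsed"]] - t0, 2)
  )
  if (inherits(res, "stage_error")) NULL else res
}

#' Run the full analysis pipeline
#'
#' Executes, in order: data synthesis (or loading), per-bone structure
#' traits, GPA and centroid size, the phylogenetic size ANOVA, shape models
#' (Pillai MANOVA on PC scores, Procrustes ANCOVA with and without the
#' Brownian transform, pairwise ecotype tests), the five-model PGLS
#' competition per structure trait and bone with bootstrap CIs and allometry
#' calls, two-block PLS between shape and structure and between bones,
#' CVA with jackknife cross-validation, and phylogenetic paired t-tests
#' between bones. Stage failures are isolated and logged, never fatal to the
#' run.
#'
#' @param config a [run_config()].
#' @return An object of class `report_bundle`: named tables, fitted objects,
#'   a stage log, and a manifest (seed, stage seeds, sizes, package version).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  lg <- new.env()
  lg$log <- list()
  bundle <- list(tables = list(), objects = list())

  dataset <- run_stage(lg, "data", {
    if (is.null(config$inputs)) {
      p <- config$params
      p$seed <- stage_seed(config$seed, "synthesis")
      simulate_dataset(p)
    } else {
      load_user_dataset(config$inputs)
    }
  })
  if (is.null(dataset)) {
    return(finish_bundle(bundle, lg, config, NULL))
  }
  bundle$objects$dataset <- dataset
  tips <- dataset$tree$tip.label
  eco <- dataset$specimens[tips, "ecotype"]
  bundle$tables$validation <- validate_inputs(
    tree = dataset$tree,
    specimens = data.frame(specimen = rownames(dataset$specimens),
                           ecotype = dataset$specimens$ecotype),
    landmark_ids = dimnames(dataset$shapes$coords)[[1]]
  )

  bones <- names(dataset$bone_specs)
  structure_tabs <- NULL
  if ("structure" %in% config$stages) {
    structure_tabs <- run_stage(lg, "structure", {
      res <- lapply(bones, function(bn) {
        vols <- lapply(dataset$bone_specs[[bn]], function(sp) {
          make_synthetic_bone(sp, spacing = config$spacing_rel * sp$b_mid)$volume
        })
        tab <- batch_structure(
          vols, data.frame(specimen = tips, bone = bn),
          fraction = config$fraction
        )
        rownames(tab) <- tab$specimen
        tab
      })
      names(res) <- bones
      res
    })
    if (!is.null(structure_tabs)) {
      bundle$tables$structure_traits <- do.call(rbind, c(structure_tabs,
                                                         make.row.names = FALSE))
    }
  }

  aligned <- NULL
  if ("gpa" %in% config$stages) {
    aligned <- run_stage(lg, "gpa", gpa(dataset$shapes))
    if (!is.null(aligned)) {
      bundle$objects$aligned <- aligned
      lncs <- log(aligned$centroid_size)
      bundle$tables$centroid_size <- data.frame(
        specimen = tips, centroid_size = aligned$centroid_size[tips],
        ln_centroid_size = lncs[tips], ecotype = eco, row.names = NULL
      )
      size_fit <- run_stage(lg, "size_anova", {
        fit <- phylo_anova(stats::setNames(lncs[tips], tips), eco, dataset$tree)
        boot <- bootstrap_coefficients(fit, n_boot = config$n_boot,
                                       seed = stage_seed(config$seed, "size_anova"))
        list(fit = fit, pairwise = pairwise_ci(boot, "means", ecotype = "group"))
      })
      if (!is.null(size_fit)) {
        bundle$tables$size_anova <- data.frame(
          R2 = size_fit$fit$R2, lambda = size_fit$fit$lambda,
          AICc = size_fit$fit$AICc
        )
        bundle$tables$size_pairwise <- size_fit$pairwise
      }
    }
  }

  if ("shape_models" %in% config$stages && !is.null(aligned)) {
    sm <- run_stage(lg, "shape_models", {
      Y <- as_shape_matrix(aligned)[tips, ]
      df <- data.frame(lnsize = log(aligned$centroid_size[tips]),
                       ecotype = factor(eco), row.names = tips)
      pca <- shape_pca(aligned, tree = dataset$tree)
      n <- length(tips)
      g <- nlevels(df$ecotype)
      cume <- cumsum(pca$percent_variance) / 100
      n_pc <- min(which(cume >= 0.95)[1], n - (g + 2L) - 2L)
      scores <- pca$scores[tips, seq_len(n_pc), drop = FALSE]
      list(
        pca = pca,
        pillai = pillai_manova(scores, ~ lnsize * ecotype, df,
                               n_perm = config$n_perm,
                               seed = stage_seed(config$seed, "pillai")),
        ancova = procrustes_lm(Y, ~ lnsize * ecotype, df,
                               n_perm = config$n_perm,
                               seed = stage_seed(config$seed, "ancova")),
        ancova_bm = procrustes_lm(Y, ~ lnsize * ecotype, df,
                                  n_perm = config$n_perm,
                                  seed = stage_seed(config$seed, "ancova_bm"),
                                  phylo = "BM", tree = dataset$tree)
      )
    })
    if (!is.null(sm)) {
      bundle$objects$shape_pca <- sm$pca
      bundle$tables$shape_pca_variance <- data.frame(
        axis = seq_along(sm$pca$percent_variance),
        percent_variance = sm$pca$percent_variance
      )
      bundle$tables$shape_pillai <- sm$pillai$table
      bundle$tables$shape_ancova <- sm$ancova$table
      bundle$tables$shape_ancova_bm <- sm$ancova_bm$table
      pw <- run_stage(lg, "shape_pairwise", {
        rbind(
          cbind(model = "nonphylogenetic",
                pairwise_groups(sm$ancova, "ecotype", n_perm = config$n_perm,
                                seed = stage_seed(config$seed, "pairwise"))),
          cbind(model = "brownian",
                pairwise_groups(sm$ancova_bm, "ecotype", n_perm = config$n_perm,
                                seed = stage_seed(config$seed, "pairwise_bm")))
        )
      })
      if (!is.null(pw)) bundle$tables$shape_pairwise <- pw
    }
  }

  if ("pgls" %in% config$stages && !is.null(structure_tabs)) {
    pg <- run_stage(lg, "pgls", {
      comp_rows <- list(); slope_rows <- list(); mean_rows <- list()
      lnsize <- if (!is.null(aligned)) log(aligned$centroid_size[tips]) else
        dataset$specimens[tips, "lnsize"]
      for (bn in bones) {
        tab <- structure_tabs[[bn]]
        for (tr in c("cg", "de", "css")) {
          df <- data.frame(y = tab[tips, tr], lnsize = lnsize,
                           ecotype = factor(eco), row.names = tips)
          cmp <- fit_model_set(df, "y", dataset$tree)
          comp_rows[[paste(bn, tr)]] <- cbind(bone = bn, trait = tr, cmp$table)
          fit_int <- cmp$fits[["size*ecotype"]]
          boot <- bootstrap_coefficients(
            fit_int, n_boot = config$n_boot,
            seed = stage_seed(config$seed, paste0("boot_", bn, "_", tr))
          )
          slope_rows[[paste(bn, tr)]] <- cbind(bone = bn, trait = tr,
                                               slope_cis(boot))
          mean_rows[[paste(bn, tr)]] <- cbind(bone = bn, trait = tr,
                                              pairwise_ci(boot, "means"))
        }
      }
      list(comparison = do.call(rbind, c(comp_rows, make.row.names = FALSE)),
           allometry = do.call(rbind, c(slope_rows, make.row.names = FALSE)),
           mean_pairwise = do.call(rbind, c(mean_rows, make.row.names = FALSE)))
    })
    if (!is.null(pg)) {
      bundle$tables$model_comparison <- pg$comparison
      bundle$tables$allometry <- pg$allometry
      bundle$tables$trait_pairwise <- pg$mean_pairwise
    }
  }

  if ("pls" %in% config$stages && !is.null(aligned) && !is.null(structure_tabs)) {
    pls <- run_stage(lg, "pls", {
      Y <- as_shape_matrix(aligned)[tips, ]
      rows <- lapply(bones, function(bn) {
        S <- as.matrix(structure_tabs[[bn]][tips, c("cg", "de", "css")])
        r <- two_block_pls(Y, S, n_perm = config$n_perm,
                           seed = stage_seed(config$seed, paste0("pls_", bn)))
        data.frame(comparison = paste0("shape_vs_structure_", bn),
                   r_pls = r$r_pls, Z = r$Z, p = r$p)
      })
      if (length(bones) >= 2L) {
        S1 <- as.matrix(structure_tabs[[bones[1]]][tips, c("cg", "de", "css")])
        S2 <- as.matrix(structure_tabs[[bones[2]]][tips, c("cg", "de", "css")])
        r <- two_block_pls(S1, S2, n_perm = config$n_perm,
                           seed = stage_seed(config$seed, "pls_bones"))
        rows <- c(rows, list(data.frame(
          comparison = paste(bones[1], "vs", bones[2], "structure"),
          r_pls = r$r_pls, Z = r$Z, p = r$p
        )))
      }
      do.call(rbind, rows)
    })
    if (!is.null(pls)) bundle$tables$pls <- pls
  }

  if ("cva" %in% config$stages && !is.null(aligned)) {
    cva <- run_stage(lg, "cva", cva_jackknife(aligned, eco))
    if (!is.null(cva)) {
      bundle$objects$cva <- cva
      bundle$tables$cva <- data.frame(
        group = c(names(cva$per_group_accuracy), "overall"),
        accuracy_pct = c(as.numeric(cva$per_group_accuracy), cva$overall_accuracy)
      )
    }
  }

  if ("ttest" %in% config$stages && !is.null(structure_tabs) && length(bones) >= 2L) {
    tt <- run_stage(lg, "ttest", {
      rows <- lapply(c("cg", "de", "css"), function(tr) {
        a <- stats::setNames(structure_tabs[[bones[1]]][tips, tr], tips)
        b <- stats::setNames(structure_tabs[[bones[2]]][tips, tr], tips)
        r <- phylo_paired_ttest(a, b, dataset$tree)
        data.frame(trait = tr, mean_diff = r$mean_diff, se = r$se, t = r$t,
                   df = r$df, p = r$p, lambda = r$lambda)
      })
      do.call(rbind, rows)
    })
    if (!is.null(tt)) bundle$tables$paired_ttest <- tt
  }

  finish_bundle(bundle, lg, config, dataset)
}

finish_bundle <- function(bundle, lg, config, dataset) {
  bundle$log <- do.call(rbind, lg$log)
  bundle$manifest <- list(
    package_version = as.character(utils::packageVersion("osteomorph")),
    seed = config$seed, n_perm = config$n_perm, n_boot = config$n_boot,
    fraction = config$fraction, stages = config$stages,
    n_tips = if (!is.null(dataset)) length(dataset$tree$tip.label) else NA,
    synthetic = is.null(config$inputs)
  )
  out <- structure(bundle, class = "report_bundle")
  if (!is.null(config$out)) make_report(out, config$out)
  out
}

#' @export
print.report_bundle <- function(x, ...) {
  cat(sprintf("<report_bundle> %d tables; stages:\n", length(x$tables)))
  print(x$log, row.names = FALSE)
  invisible(x)
}

# minimal user-data loader: tree + specimen table + landmarks (+ volumes)
load_user_dataset <- function(inputs) {
  tree <- ape::read.tree(inputs$tree)
  specimens <- utils::read.csv(inputs$specimens, stringsAsFactors = FALSE)
  if (anyDuplicated(specimens$specimen)) stopf("duplicated specimen ids")
  rownames(specimens) <- specimens$specimen
  miss <- setdiff(tree$tip.label, specimens$specimen)
  if (length(miss)) stopf("specimen table is missing tips: %s",
                          paste(miss, collapse = ", "))
  shapes <- read_landmarks(inputs$landmarks)
  specimens$ecotype <- factor(specimens$ecotype)
  bone_specs <- list()
  if (!is.null(inputs$volumes)) {
    stopf("volume loading through run_pipeline requires batch_structure(); pass synthetic inputs or run the structure stage manually")
  }
  list(tree = tree, specimens = specimens, shapes = shapes,
       bone_specs = bone_specs, ground_truth = NULL)
}

#' Write a report bundle to disk
#'
#' One CSV per table, a JSON manifest, and a human-readable markdown summary
#' with the model-comparison grid and the allometry verdict grid. All numbers
#' in the summary are traceable to the CSVs; re-rendering from the saved CSVs
#' gives an identical summary.
#'
#' @param bundle a `report_bundle` from [run_pipeline()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
make_report <- function(bundle, dir) {
  stopifnot(inherits(bundle, "report_bundle"))
  ok <- dir.exists(dir) || dir.create(dir, recursive = TRUE)
  if (!ok) stopf("cannot create output directory '%s'", dir)
  for (nm in names(bundle$tables)) {
    utils::write.csv(bundle$tables[[nm]], file.path(dir, paste0(nm, ".csv")),
                     row.names = FALSE)
  }
  utils::write.csv(bundle$log, file.path(dir, "stage_log.csv"), row.names = FALSE)
  jsonlite::write_json(bundle$manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)

  lines <- c("# Analysis report", "")
  if (!length(bundle$tables)) {
    lines <- c(lines, "No stages produced output.")
  } else {
    if (!is.null(bundle$tables$model_comparison)) {
      lines <- c(lines, "## Model comparison (AICc)", "",
                 df_to_md(bundle$tables$model_comparison), "")
    }
    if (!is.null(bundle$tables$allometry)) {
      lines <- c(lines, "## Allometry verdicts", "",
                 df_to_md(bundle$tables$allometry), "")
    }
    other <- setdiff(names(bundle$tables), c("model_comparison", "allometry"))
    lines <- c(lines, "## Tables written",
               paste0("- ", other, ".csv"))
  }
  writeLines(lines, file.path(dir, "summary.md"))
  invisible(dir)
}

# plain markdown table, numbers at fixed precision for byte-stable output
df_to_md <- function(df, digits = 4) {
  fmt <- function(x) {
    if (is.numeric(x)) formatC(x, digits = digits, format = "g") else as.character(x)
  }
  cells <- vapply(df, fmt, character(nrow(df)))
  cells <- matrix(cells, nrow = nrow(df))
  header <- paste0("| ", paste(names(df), collapse = " | "), " |")
  sep <- paste0("|", paste(rep("---", ncol(df)), collapse = "|"), "|")
  body <- apply(cells, 1, function(r) paste0("| ", paste(r, collapse = " | "), " |"))
  c(header, sep, body)
}
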