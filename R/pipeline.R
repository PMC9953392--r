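#' Pipeline configuration
#'
#' Bundles the cohort generator settings with the inference parameters of
#' a full run. Every random stage has an explicit seed derived from
#' `seed`. The three standard second-level analyses mirror the design of
#' the study the package models: the plain condition contrast
#' (intercept-only design), and one covariate analysis per affect change
#' (design = intercept + that covariate, contrast on the covariate).
#'
#' @param cohort A [cohort_config()].
#' @param p_height Height threshold for the main analyses (default 0.001).
#' @param n_perm Permutations per NBS run (default 1000).
#' @param seed Master seed (default the cohort's seed).
#' @param denoise Run the denoising stage (default TRUE).
#' @param sweep_thresholds `NULL` (no sweep) or decreasing numeric vector.
#' @param alpha Component significance level (default 0.05).
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(cohort = cohort_config(), p_height = 0.001,
                            n_perm = 1000, seed = cohort$seed,
                            denoise = TRUE, sweep_thresholds = NULL,
                            alpha = 0.05) {
  cfg <- list(cohort = cohort, p_height = p_height, n_perm = n_perm,
              seed = as.integer(seed), denoise = denoise,
              sweep_thresholds = sweep_thresholds, alpha = alpha)
  class(cfg) <- "pipeline_config"
  cfg
}

stage_log <- function(log, stage, t0, ...) {
  info <- list(...)
  info$stage <- stage
  info$seconds <- round(as.numeric(Sys.time()) - t0, 2)
  message(sprintf("[%s] done in %.1fs", stage, info$seconds))
  c(log, list(info))
}

#' Run the full synthetic-cohort analysis pipeline
#'
#' simulate -> denoise -> connectivity -> behaviour -> NBS (condition,
#' positive-affect and negative-affect covariate analyses, plus the
#' both-covariate control contrast) -> optional threshold sweep. Writes
#' the cohort TSVs, PANAS CSV, behaviour JSON, edge-stats TSV, component
#' reports and a manifest with seeds and per-stage counts under
#' `out_dir`. Deterministic: rerunning with the same config reproduces
#' identical numbers.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Output directory.
#' @return Invisibly, a list with `behaviour`, `nbs` (named list of
#'   `nbs_result`), `sweep` (or NULL), `matrices`, `design`s and
#'   `manifest`.
#' @export
run_pipeline <- function(config, out_dir) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log <- list()

  t0 <- as.numeric(Sys.time())
  cohort <- simulate_cohort(config$cohort)
  panas <- simulate_panas_cohort(config$cohort)
  write_cohort(cohort, file.path(out_dir, "cohort"))
  write_panas_csv(panas, file.path(out_dir, "panas.csv"))
  log <- stage_log(log, "simulate", t0, n_series = length(cohort$series),
                   n_panas = length(panas))

  t0 <- as.numeric(Sys.time())
  series <- cohort$series
  if (config$denoise) {
    series <- lapply(series, denoise_series)
  }
  log <- stage_log(log, "denoise", t0, enabled = config$denoise)

  t0 <- as.numeric(Sys.time())
  matrices <- build_rrc(series)
  log <- stage_log(log, "connectivity", t0, n_matrices = length(matrices))

  t0 <- as.numeric(Sys.time())
  scores <- score_panas_cohort(panas)
  lmm <- fit_affect_lmm(scores)
  pre <- panas[vapply(panas, function(r) r$condition == "pre", logical(1))]
  post <- panas[vapply(panas, function(r) r$condition == "post",
                       logical(1))]
  items <- item_shift_tests(pre, post)
  pre_s <- scores[scores$condition == "pre", ]
  post_s <- scores[scores$condition == "post", ]
  behaviour <- list(
    lmm = list(anova = lmm$anova, contrasts = lmm$contrasts,
               lrt = lmm$lrt, var_share = lmm$var_share),
    items = items,
    positivity_ratio = list(pre = positivity_ratio(mean(pre_s$pa_total),
                                                   mean(pre_s$na_total)),
                            post = positivity_ratio(mean(post_s$pa_total),
                                                    mean(post_s$na_total))),
    pa_correlation = affect_correlation(pre_s$pa_total, post_s$pa_total))
  jsonlite::write_json(
    list(lmm = list(anova = behaviour$lmm$anova,
                    contrasts = behaviour$lmm$contrasts,
                    lrt = behaviour$lmm$lrt,
                    var_share = behaviour$lmm$var_share),
         items = items, positivity_ratio = behaviour$positivity_ratio),
    file.path(out_dir, "behaviour.json"), auto_unbox = TRUE, digits = NA,
    dataframe = "rows")
  log <- stage_log(log, "behaviour", t0, n_items = nrow(items))

  t0 <- as.numeric(Sys.time())
  atlas <- config$cohort$atlas
  pa_scores <- score_panas_cohort(panas)
  dpa <- merge(pa_scores[pa_scores$condition == "post", ],
               pa_scores[pa_scores$condition == "pre", ], by = "subject",
               suffixes = c("_post", "_pre"))
  covs <- data.frame(subject = dpa$subject,
                     dPA = dpa$pa_total_post - dpa$pa_total_pre,
                     dNA = dpa$na_total_post - dpa$na_total_pre)
  utils::write.csv(covs, file.path(out_dir, "affect_changes.csv"),
                   row.names = FALSE)

  designs <- list(
    condition = build_design(matrices, atlas),
    positive = build_design(matrices, atlas, covs, "dPA"),
    negative = build_design(matrices, atlas, covs, "dNA"),
    control = build_design(matrices, atlas, covs, c("dPA", "dNA")))
  contrasts <- list(condition = c(intercept = 1), positive = c(dPA = 1),
                    negative = c(dNA = 1),
                    control = c(dPA = -1, dNA = 1))
  nbs <- list()
  for (nm in names(designs)) {
    res <- run_nbs(designs[[nm]], contrasts[[nm]],
                   p_height = config$p_height, n_perm = config$n_perm,
                   seed = config$seed + match(nm, names(designs)),
                   alpha = config$alpha)
    stats_path <- file.path(out_dir, paste0("edges_", nm, ".tsv"))
    supra <- threshold_edges(res$stats, config$p_height)
    tab <- res$stats
    tab$suprathreshold <- tab$p < config$p_height
    utils::write.table(tab, stats_path, sep = "\t", row.names = FALSE,
                       quote = FALSE)
    write_component_report(res$components,
                           file.path(out_dir,
                                     paste0("components_", nm, ".json")),
                           atlas = atlas)
    nbs[[nm]] <- res
  }
  log <- stage_log(log, "nbs", t0,
                   n_components = vapply(nbs, function(r)
                     length(r$components), integer(1)))

  sweep <- NULL
  if (!is.null(config$sweep_thresholds)) {
    t0 <- as.numeric(Sys.time())
    sweep <- threshold_sweep(designs$condition, c(intercept = 1),
                             thresholds = config$sweep_thresholds,
                             n_perm = config$n_perm,
                             seed = config$seed + 100,
                             alpha = config$alpha)
    jsonlite::write_json(sweep$families,
                         file.path(out_dir, "sweep_families.json"),
                         auto_unbox = TRUE, digits = NA,
                         dataframe = "rows")
    log <- stage_log(log, "sweep", t0, n_thresholds =
                       length(config$sweep_thresholds))
  }

  manifest <- list(
    seed = config$seed, p_height = config$p_height,
    n_perm = config$n_perm, alpha = config$alpha,
    denoise = config$denoise,
    n_subjects = config$cohort$n_subjects,
    n_volumes = config$cohort$n_volumes,
    n_matrices = length(matrices),
    stages = log)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(list(behaviour = behaviour, nbs = nbs, sweep = sweep,
                 matrices = matrices, designs = designs,
                 covariates = covs,
                 manifest = file.path(out_dir, "manifest.json")))
}

#' Summary figures for a pipeline run
#'
#' A violin plot of the PANAS subscale totals by condition, and, for each
#' significant component of a covariate analysis, a panel of per-edge
#' scatter plots of the affect change against the edge's connectivity
#' change with its effect-size interval in the caption.
#'
#' @param results Return value of [run_pipeline()].
#' @param dir Output directory for the figure files.
#' @param panas Optional list of `panas_record` used for the violin plot;
#'   defaults to regenerating from the run's cohort config is not
#'   attempted - the scores stored in `results$behaviour` are not item
#'   level, so pass records when a violin is wanted.
#' @return Character vector of files written (empty, with a warning, when
#'   there is nothing to plot).
#' @export
plot_summaries <- function(results, dir, panas = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- character(0)
  if (!is.null(panas)) {
    scores <- score_panas_cohort(panas)
    long <- rbind(data.frame(condition = scores$condition, affect = "PA",
                             total = scores$pa_total),
                  data.frame(condition = scores$condition, affect = "NA",
                             total = scores$na_total))
    long$condition <- factor(long$condition, levels = c("pre", "post"))
    p <- ggplot2::ggplot(long, ggplot2::aes(x = condition, y = total,
                                            fill = affect)) +
      ggplot2::geom_violin(alpha = 0.6) +
      ggplot2::stat_summary(fun = mean, geom = "point",
                            position = ggplot2::position_dodge(0.9)) +
      ggplot2::facet_wrap(~affect) +
      ggplot2::labs(y = "PANAS subscale total", x = NULL) +
      ggplot2::theme_minimal()
    f <- file.path(dir, "panas_violin.png")
    ggplot2::ggsave(f, p, width = 6, height = 4, dpi = 120)
    files <- c(files, f)
  }
  for (nm in c("positive", "negative")) {
    res <- results$nbs[[nm]]
    if (is.null(res)) next
    design <- results$designs[[nm]]
    covname <- if (nm == "positive") "dPA" else "dNA"
    sig <- Filter(function(cp) isTRUE(cp$significant), res$components)
    for (ci in seq_along(sig)) {
      cp <- sig[[ci]]
      panels <- do.call(rbind, lapply(seq_len(nrow(cp$edges)), function(k) {
        i <- roi_index(design$atlas, cp$edges$roi_i[k])
        j <- roi_index(design$atlas, cp$edges$roi_j[k])
        col <- which(design$edges$pairs$i == min(i, j) &
                       design$edges$pairs$j == max(i, j))
        data.frame(edge = paste(cp$edges$roi_i[k], cp$edges$roi_j[k],
                                sep = " - "),
                   covariate = design$X[, covname],
                   dz = design$D[, col])
      }))
      p <- ggplot2::ggplot(panels, ggplot2::aes(x = covariate, y = dz)) +
        ggplot2::geom_point() +
        ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = TRUE,
                             level = 0.90) +
        ggplot2::facet_wrap(~edge, scales = "free_y") +
        ggplot2::labs(x = paste("change in", covname),
                      y = "z(post) - z(pre)") +
        ggplot2::theme_minimal()
      f <- file.path(dir, sprintf("component_%s_%d.png", nm, ci))
      ggplot2::ggsave(f, p, width = 7, height = 5, dpi = 120)
      files <- c(files, f)
    }
  }
  if (!length(files)) warning("nothing to plot; no files written")
  files
}
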