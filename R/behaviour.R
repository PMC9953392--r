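#' Score a PANAS record into subscale totals
#'
#' Sums the 10 positive-affect and 10 negative-affect items (standard
#' 20-item schedule assignment, see [panas_items()]). Each subscale total
#' therefore lies in 10..50.
#'
#' @param record A `panas_record` (or list with `subject_id`, `condition`,
#'   `items`: named integer vector).
#' @return List of class `affect_scores`: `subject_id`, `condition`,
#'   `pa_total`, `na_total`.
#' @examples
#' rec <- list(subject_id = "s01", condition = "pre",
#'             items = setNames(rep(3L, 20),
#'                              unlist(panas_items(), use.names = FALSE)))
#' score_panas(rec)$pa_total  # 30
#' @export
score_panas <- function(record) {
  it <- panas_items()
  items <- record$items
  all_names <- c(it$pa, it$na)
  missing <- setdiff(all_names, names(items))
  if (length(missing)) {
    stop("missing PANAS item(s): ", paste(missing, collapse = ", "))
  }
  vals <- items[all_names]
  bad <- all_names[!(vals %in% 1:5)]
  if (length(bad)) {
    stop("PANAS item(s) out of range 1..5: ", paste(bad, collapse = ", "))
  }
  out <- list(subject_id = record$subject_id, condition = record$condition,
              pa_total = as.integer(sum(vals[it$pa])),
              na_total = as.integer(sum(vals[it$na])))
  class(out) <- "affect_scores"
  out
}

#' Score a list of PANAS records into a data frame
#' @param records List of `panas_record` objects.
#' @return data.frame with `subject`, `condition`, `pa_total`, `na_total`.
#' @export
score_panas_cohort <- function(records) {
  do.call(rbind, lapply(records, function(r) {
    s <- score_panas(r)
    data.frame(subject = s$subject_id, condition = s$condition,
               pa_total = s$pa_total, na_total = s$na_total)
  }))
}

#' Positivity ratio
#'
#' Ratio of mean positive to mean negative affect, the classic
#' "flourishing" summary with its proposed critical value of 3:1.
#'
#' @param pa_mean Mean positive-affect total.
#' @param na_mean Mean negative-affect total; must be > 0.
#' @return The ratio rounded to 2 decimals.
#' @examples
#' positivity_ratio(29.28, 16.75)  # 1.75
#' positivity_ratio(36.28, 12.09)  # 3.00
#' @export
positivity_ratio <- function(pa_mean, na_mean) {
  if (!is.finite(na_mean) || na_mean <= 0) {
    stop("na_mean must be a positive number")
  }
  round(pa_mean / na_mean, 2)
}

#' Linear mixed model on PANAS subscale totals
#'
#' Fits, by maximum likelihood, `score ~ affect * condition + (1 |
#' subject)` on the long form of the scores (affect: positive/negative;
#' condition: pre/post), with sum-to-zero contrasts. Reports Type-III F
#' tests with Satterthwaite denominator df, post-hoc post-minus-pre
#' contrasts within each affect (Bonferroni over the two contrasts), the
#' likelihood-ratio test of the random intercept against the
#' fixed-effects-only model (2 x difference in log-likelihood, chi-square
#' df 1), and the share of variance attributed to subjects.
#'
#' @param scores data.frame with `subject`, `condition` (`"pre"`/`"post"`),
#'   `pa_total`, `na_total`; subjects lacking either condition are dropped
#'   with a message.
#' @return List of class `affect_lmm`: `anova` (effect, F, df1, df2, p),
#'   `contrasts` (affect, MD, SE, t, df, p), `lrt` (statistic, df, p),
#'   `var_share`, `n_subjects`, and the fitted `model`.
#' @export
fit_affect_lmm <- function(scores) {
  stopifnot(all(c("subject", "condition", "pa_total", "na_total") %in%
                  names(scores)))
  have_both <- tapply(scores$condition, scores$subject,
                      function(cc) all(c("pre", "post") %in% cc))
  keep <- names(have_both)[have_both]
  dropped <- setdiff(unique(scores$subject), keep)
  if (length(dropped)) {
    message("dropping subject(s) without both conditions: ",
            paste(dropped, collapse = ", "))
  }
  scores <- scores[scores$subject %in% keep, ]
  if (length(keep) < 2) stop("need >= 2 subjects with both conditions")
  long <- rbind(
    data.frame(subject = scores$subject, condition = scores$condition,
               affect = "positive", score = scores$pa_total),
    data.frame(subject = scores$subject, condition = scores$condition,
               affect = "negative", score = scores$na_total))
  long$affect <- factor(long$affect, levels = c("positive", "negative"))
  long$condition <- factor(long$condition, levels = c("pre", "post"))
  long$subject <- factor(long$subject)

  model <- lmerTest::lmer(
    score ~ affect * condition + (1 | subject), data = long, REML = FALSE,
    contrasts = list(affect = "contr.sum", condition = "contr.sum"))
  av <- stats::anova(model, type = 3)
  anova_df <- data.frame(effect = rownames(av), F = av[["F value"]],
                         df1 = av$NumDF, df2 = av$DenDF,
                         p = av[["Pr(>F)"]], row.names = NULL)

  emm <- emmeans::emmeans(model, ~ condition | affect)
  ctr <- summary(emmeans::contrast(emm, "revpairwise"), by = NULL,
                 adjust = "bonferroni", infer = c(FALSE, TRUE))
  contrasts <- data.frame(affect = as.character(ctr$affect),
                          MD = ctr$estimate, SE = ctr$SE, t = ctr$t.ratio,
                          df = ctr$df, p = ctr$p.value)

  null_model <- stats::lm(score ~ affect * condition, data = long)
  lrt_stat <- max(0, 2 * (as.numeric(stats::logLik(model)) -
                            as.numeric(stats::logLik(null_model))))
  lrt <- list(statistic = lrt_stat, df = 1,
              p = stats::pchisq(lrt_stat, 1, lower.tail = FALSE))

  vc <- as.data.frame(lme4::VarCorr(model))
  v_subj <- vc$vcov[vc$grp == "subject"]
  v_res <- vc$vcov[vc$grp == "Residual"]
  out <- list(anova = anova_df, contrasts = contrasts, lrt = lrt,
              var_share = v_subj / (v_subj + v_res),
              n_subjects = length(keep), model = model)
  class(out) <- "affect_lmm"
  out
}

#' @export
print.affect_lmm <- function(x, ...) {
  cat("PANAS linear mixed model (", x$n_subjects, " subjects)\n", sep = "")
  print(x$anova, digits = 4)
  cat("post-hoc post - pre contrasts (Bonferroni):\n")
  print(x$contrasts, digits = 4)
  cat(sprintf("random intercept: LRT = %.3f (df 1, p = %.3f), %.1f%% of variance\n",
              x$lrt$statistic, x$lrt$p, 100 * x$var_share))
  invisible(x)
}

#' Per-item pre/post shift tests with Bayes factors
#'
#' For every PANAS item, a paired Wilcoxon signed-rank test (zero
#' differences dropped, normal approximation) plus a default-prior JZS
#' Bayes factor ([bf_ttest()]) on the item differences, banded into
#' evidence classes. When pre and post are identical for an item the
#' difference t statistic is taken as 0, giving a well-defined BF10 < 1
#' and p = 1.
#'
#' @param pre,post Lists of `panas_record` for the two conditions; matched
#'   by `subject_id`.
#' @return data.frame: `item`, `subscale`, `statistic` (signed-rank V),
#'   `p`, `bf10`, `evidence_class`, `median_diff`.
#' @export
item_shift_tests <- function(pre, post) {
  pre_ids <- vapply(pre, function(r) r$subject_id, character(1))
  post_ids <- vapply(post, function(r) r$subject_id, character(1))
  common <- intersect(pre_ids, post_ids)
  if (length(common) < 3) stop("need >= 3 paired subjects")
  pre_m <- do.call(rbind, lapply(pre[match(common, pre_ids)],
                                 function(r) r$items))
  post_m <- do.call(rbind, lapply(post[match(common, post_ids)],
                                  function(r) r$items))
  it <- panas_items()
  out <- lapply(c(it$pa, it$na), function(item) {
    x <- post_m[, item]; y <- pre_m[, item]
    d <- x - y
    if (all(d == 0)) {
      v <- 0; p <- 1; tstat <- 0
    } else {
      wt <- suppressWarnings(stats::wilcox.test(x, y, paired = TRUE,
                                                exact = FALSE))
      v <- unname(wt$statistic); p <- wt$p.value
      tstat <- if (stats::sd(d) == 0) sign(mean(d)) * Inf else
        mean(d) / (stats::sd(d) / sqrt(length(d)))
    }
    bf <- bf_ttest(tstat, length(d))
    data.frame(item = item,
               subscale = if (item %in% it$pa) "PA" else "NA",
               statistic = v, p = p, bf10 = bf,
               evidence_class = bf_evidence_class(bf),
               median_diff = stats::median(d))
  })
  do.call(rbind, out)
}

#' Pearson correlation with CI and default-prior Bayes factor
#'
#' @param x,y Paired numeric vectors, n >= 4, non-degenerate.
#' @param conf Confidence level for the Fisher-z interval (default 0.95).
#' @return List: `r`, `ci`, `p`, `bf10`, `n`.
#' @export
affect_correlation <- function(x, y, conf = 0.95) {
  stopifnot(length(x) == length(y))
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 4) stop("need >= 4 complete pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("zero variance in one of the inputs")
  }
  ct <- stats::cor.test(x, y, conf.level = conf)
  r <- unname(ct$estimate)
  bf <- bf_pearson(r, length(x))
  list(r = r, ci = as.numeric(ct$conf.int), p = ct$p.value, bf10 = bf,
       n = length(x))
}

#' Welch two-sample t test
#'
#' Unequal-variance t test with Welch-Satterthwaite degrees of freedom.
#'
#' @param group1,group2 Numeric vectors, each n >= 2.
#' @param conf Confidence level (default 0.95).
#' @return List: `t`, `df`, `p`, `MD` (mean group1 - group2), `ci`.
#' @export
welch_group_test <- function(group1, group2, conf = 0.95) {
  group1 <- group1[is.finite(group1)]; group2 <- group2[is.finite(group2)]
  if (length(group1) < 2 || length(group2) < 2) {
    stop("each group needs >= 2 observations")
  }
  if (stats::sd(group1) == 0 && stats::sd(group2) == 0) {
    if (mean(group1) == mean(group2)) {
      return(list(t = 0, df = length(group1) + length(group2) - 2, p = 1,
                  MD = 0, ci = c(0, 0)))
    }
    stop("degenerate groups with zero variance")
  }
  tt <- stats::t.test(group1, group2, var.equal = FALSE, conf.level = conf)
  list(t = unname(tt$statistic), df = unname(tt$parameter), p = tt$p.value,
       MD = unname(diff(rev(tt$estimate))), ci = as.numeric(tt$conf.int))
}

#' Paired comparison with effect size and Bayes factor
#'
#' Paired t test with Cohen's d computed on the differences
#' (`mean(diff) / sd(diff)`), a noncentral-t confidence interval for d,
#' and a default-prior JZS Bayes factor.
#'
#' @param baseline,response Paired numeric vectors, n >= 3.
#' @param conf Confidence level for the d interval (default 0.95).
#' @return List: `t`, `df`, `p`, `MD` (response - baseline), `cohen_d`,
#'   `d_ci`, `bf10`, `n`.
#' @export
paired_effect <- function(baseline, response, conf = 0.95) {
  stopifnot(length(baseline) == length(response))
  d <- response - baseline
  d <- d[is.finite(d)]
  n <- length(d)
  if (n < 3) stop("need >= 3 complete pairs")
  sdd <- stats::sd(d)
  if (sdd == 0) {
    tstat <- if (mean(d) == 0) 0 else sign(mean(d)) * Inf
    dd <- if (mean(d) == 0) 0 else sign(mean(d)) * Inf
    return(list(t = tstat, df = n - 1,
                p = if (tstat == 0) 1 else 0, MD = mean(d),
                cohen_d = dd, d_ci = c(dd, dd), bf10 = bf_ttest(tstat, n),
                n = n))
  }
  tstat <- mean(d) / (sdd / sqrt(n))
  list(t = tstat, df = n - 1,
       p = 2 * stats::pt(-abs(tstat), n - 1), MD = mean(d),
       cohen_d = mean(d) / sdd, d_ci = cohen_d_ci(tstat, n, conf),
       bf10 = bf_ttest(tstat, n), n = n)
}

#' Largest single-breath inspired volume after immersion onset
#'
#' The inspiratory gasp is read off a breath-event trace as the maximum
#' inspired volume within the first `window` seconds of entering the
#' water.
#'
#' @param breaths data.frame with `time` (s) and `volume` (L).
#' @param immersion_start Time (s) the foot enters the water.
#' @param window Detection window in seconds (default 10).
#' @param trace_end End of the recorded trace; defaults to the last breath
#'   time. The trace must cover the full window.
#' @return Gasp volume in litres; 0 with a warning if no breath falls in
#'   the window (apnoea).
#' @export
inspiratory_gasp <- function(breaths, immersion_start, window = 10,
                             trace_end = max(breaths$time)) {
  stopifnot(all(c("time", "volume") %in% names(breaths)))
  if (trace_end < immersion_start + window) {
    stop("trace does not cover the first ", window,
         " s of immersion (ends at ", trace_end, " s)")
  }
  inwin <- breaths$time >= immersion_start &
    breaths$time <= immersion_start + window
  if (!any(inwin)) {
    warning("no breath within the immersion window; returning 0")
    return(0)
  }
  max(breaths$volume[inwin])
}

#' Non-overlapping interval means of a uniformly sampled trace
#'
#' Averages a trace over consecutive bins of `interval` seconds; a partial
#' final bin is dropped.
#'
#' @param trace data.frame whose first column is `time` (s, uniform) and
#'   second column the values.
#' @param interval Bin width in seconds (default 10).
#' @return data.frame with `bin_start` (s) and `mean`.
#' @export
interval_means <- function(trace, interval = 10) {
  stopifnot(interval > 0, nrow(trace) >= 1)
  tt <- trace[[1]]; vv <- trace[[2]]
  dt <- if (length(tt) > 1) stats::median(diff(tt)) else interval
  duration <- length(tt) * dt
  n_bins <- floor(duration / interval + 1e-9)
  if (n_bins < 1) return(data.frame(bin_start = numeric(0), mean = numeric(0)))
  idx <- floor((tt - tt[1]) / interval + 1e-9)
  keep <- idx < n_bins
  means <- tapply(vv[keep], idx[keep], mean)
  data.frame(bin_start = tt[1] + as.numeric(names(means)) * interval,
             mean = as.numeric(means))
}
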