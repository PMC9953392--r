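#' Configuration for a synthetic pre/post cohort
#'
#' Bundles every parameter of the synthetic-data generator. Defaults emulate
#' the study design the package targets: 31 complete subjects scanned in two
#' resting-state sessions (pre/post immersion) of 292 volumes at TR 2.68 s
#' over a 30-ROI cortical atlas, with cohort-level affect changes of +7
#' (positive) and -4.66 (negative) PANAS points.
#'
#' Condition effects on connectivity are specified on the Fisher-z scale of
#' the target correlations: `planted_edges` raises/lowers specific edges in
#' the post condition by a fixed `delta_z`, while `covariate_coupling` ties a
#' subject's post-minus-pre z-shift on an edge to that subject's affect
#' change, `beta * (covariate - configured mean)`. Coupling to the centred
#' covariate plants a pure brain-behaviour association without any
#' group-mean connectivity shift.
#'
#' @param n_subjects Number of subjects (default 31).
#' @param n_volumes Volumes per session (default 292).
#' @param tr_seconds Repetition time in seconds (default 2.68).
#' @param base_within_network_corr Baseline correlation between ROIs of the
#'   same network (default 0.4).
#' @param base_between_network_corr Baseline correlation between ROIs of
#'   different networks (default 0.1).
#' @param planted_edges `NULL` or data.frame with columns `roi_i`, `roi_j`
#'   (atlas labels) and `delta_z` (condition z-shift).
#' @param covariate_coupling `NULL` or data.frame with columns `roi_i`,
#'   `roi_j`, `beta` (z-units per covariate unit) and `covariate`
#'   (`"dPA"` or `"dNA"`).
#' @param pa_shift_mean,pa_shift_sd Mean and SD of the per-subject change in
#'   the PANAS positive-affect total (defaults 7 and 2.5).
#' @param na_shift_mean,na_shift_sd Same for negative affect (defaults
#'   -4.66 and 2.5). The latent shift spread is the same for both
#'   subscales; their total variabilities still differ because the ordinal
#'   1-5 items add more measurement noise mid-scale (positive items) than
#'   near the floor (negative items), and because the negative subscale
#'   starts close to its floor of 10.
#' @param motion_spike_rate Per-frame probability of a head-motion spike
#'   whose framewise displacement exceeds 0.9 mm (default 0.01).
#' @param noise_leak Amplitude of physiological/noise-ROI signal leaked into
#'   the ROI data (default 0.15).
#' @param spike_artifact_sd SD of the global intensity artifact added to the
#'   BOLD data at spiked frames (default 2.5).
#' @param n_noise_rois Number of surrogate noise-ROI signals, split evenly
#'   into "wm" and "csf" sets (default 10).
#' @param hr_step_mean Mean heart-rate increase on immersion in
#'   beats min^-1 (default 10.61).
#' @param tidal_step_mean Mean tidal-volume increase on immersion in litres
#'   (default 0.44).
#' @param gasp_volume_mean Mean volume of the initial inspiratory gasp in
#'   litres (default 2).
#' @param baseline_seconds,immersion_seconds Durations of the seated
#'   baseline and the immersion (defaults 120 and 300 s).
#' @param water_temp_mean,water_temp_sd Water temperature distribution in
#'   degrees Celsius (defaults 19.93 and 0.13).
#' @param panas_subject_sd SD of the subject-level latent intercept shared
#'   by all PANAS items (default 0.15, giving a small random-intercept
#'   variance share).
#' @param seed Integer seed; identical seeds give identical cohorts.
#' @param atlas An `nbs_atlas` (default [build_default_atlas()]).
#' @return An object of class `cohort_config` (a list of the above).
#' @export
cohort_config <- function(n_subjects = 31L, n_volumes = 292L,
                          tr_seconds = 2.68,
                          base_within_network_corr = 0.4,
                          base_between_network_corr = 0.1,
                          planted_edges = NULL,
                          covariate_coupling = NULL,
                          pa_shift_mean = 7, pa_shift_sd = 2.5,
                          na_shift_mean = -4.66, na_shift_sd = 2.5,
                          motion_spike_rate = 0.01,
                          noise_leak = 0.15,
                          spike_artifact_sd = 2.5,
                          n_noise_rois = 10L,
                          hr_step_mean = 10.61,
                          tidal_step_mean = 0.44,
                          gasp_volume_mean = 2,
                          baseline_seconds = 120,
                          immersion_seconds = 300,
                          water_temp_mean = 19.93, water_temp_sd = 0.13,
                          panas_subject_sd = 0.15,
                          seed = 1L,
                          atlas = build_default_atlas()) {
  stopifnot(n_subjects >= 1, n_volumes >= 8, tr_seconds > 0,
            base_within_network_corr > 0, base_within_network_corr < 1,
            base_between_network_corr >= 0, base_between_network_corr < 1,
            motion_spike_rate >= 0, motion_spike_rate <= 1,
            inherits(atlas, "nbs_atlas"))
  check_edge_table <- function(tab, cols) {
    if (is.null(tab)) return(NULL)
    tab <- as.data.frame(tab)
    stopifnot(all(cols %in% names(tab)))
    roi_index(atlas, tab$roi_i)
    roi_index(atlas, tab$roi_j)
    if (any(tab$roi_i == tab$roi_j)) stop("self-edges are not allowed")
    tab
  }
  planted_edges <- check_edge_table(planted_edges,
                                    c("roi_i", "roi_j", "delta_z"))
  covariate_coupling <- check_edge_table(covariate_coupling,
                                         c("roi_i", "roi_j", "beta",
                                           "covariate"))
  if (!is.null(covariate_coupling) &&
      !all(covariate_coupling$covariate %in% c("dPA", "dNA"))) {
    stop("covariate_coupling$covariate must be 'dPA' or 'dNA'")
  }
  cfg <- as.list(environment())
  cfg$check_edge_table <- NULL
  cfg$seed <- as.integer(seed)
  class(cfg) <- "cohort_config"
  cfg
}

## Baseline target correlation: block-constant over networks.
base_correlation_matrix <- function(config) {
  atlas <- config$atlas
  same <- outer(atlas$network_of, atlas$network_of, "==")
  r <- ifelse(same, config$base_within_network_corr,
              config$base_between_network_corr)
  diag(r) <- 1
  dimnames(r) <- list(atlas$roi_names, atlas$roi_names)
  r
}

## Apply z-scale shifts to a correlation matrix for one subject/condition.
shifted_correlation <- function(r_base, shifts, atlas) {
  if (nrow(shifts) == 0L) return(r_base)
  z <- atanh(r_base)
  for (k in seq_len(nrow(shifts))) {
    i <- roi_index(atlas, shifts$roi_i[k])
    j <- roi_index(atlas, shifts$roi_j[k])
    z[i, j] <- z[i, j] + shifts$dz[k]
    z[j, i] <- z[i, j]
  }
  r <- tanh(z)
  diag(r) <- 1
  r
}

chol_or_fail <- function(r, config) {
  ch <- tryCatch(chol(r), error = function(e) NULL)
  if (is.null(ch)) {
    edges <- character(0)
    if (!is.null(config$planted_edges)) {
      edges <- c(edges, paste0(config$planted_edges$roi_i, "--",
                               config$planted_edges$roi_j))
    }
    if (!is.null(config$covariate_coupling)) {
      edges <- c(edges, paste0(config$covariate_coupling$roi_i, "--",
                               config$covariate_coupling$roi_j))
    }
    stop("target covariance is not positive definite; ",
         "offending planted/coupled edges: ",
         if (length(edges)) paste(edges, collapse = ", ") else "<none>")
  }
  ch
}

## Deterministic sub-seed for a subject/condition stream, kept below 2^31.
stream_seed <- function(seed, subject, condition, what = 0L) {
  base <- (abs(as.integer(seed)) %% 1000003L)
  (base * 1009L + subject * 211L +
     ifelse(condition == "post", 101L, 0L) + what * 37L) %% 2147483629L
}

#' Simulate head motion and noise-ROI signals for one session
#'
#' Motion is a smooth 6-parameter random walk (3 translations in mm, 3
#' rotations in rad). With probability `motion_spike_rate` per frame a
#' translation jump of 1.2--1.8 mm is injected, guaranteeing a framewise
#' displacement above the 0.9 mm scrubbing threshold at that frame. Noise
#' ROIs combine a slow drift, respiratory- (~0.3 Hz) and cardiac-band
#' (~1.1 Hz, aliased at the TR) sinusoids, and white noise; in the cohort
#' generator a fraction of these signals is leaked into the ROI data so
#' that nuisance regression has something real to remove.
#'
#' @param config A [cohort_config()].
#' @param subject Integer subject index.
#' @param condition `"pre"` or `"post"`.
#' @return List with `motion` (T x 6 matrix), `noise_rois` (T x k matrix,
#'   columns `wm*`/`csf*`), and `outlier_truth` (logical ground-truth spike
#'   indicator per frame).
#' @export
simulate_motion_and_noise <- function(config, subject, condition) {
  stopifnot(inherits(config, "cohort_config"),
            condition %in% c("pre", "post"))
  nt <- config$n_volumes
  withr::with_seed(stream_seed(config$seed, subject, condition, 1L), {
    trans <- apply(matrix(stats::rnorm(nt * 3, sd = 0.02), nt, 3), 2, cumsum)
    rot <- apply(matrix(stats::rnorm(nt * 3, sd = 4e-4), nt, 3), 2, cumsum)
    spikes <- stats::runif(nt) < config$motion_spike_rate
    spikes[1] <- FALSE  # FD is undefined at the first frame
    if (any(spikes)) {
      for (f in which(spikes)) {
        jump <- sample(c(-1, 1), 1) * stats::runif(1, 1.2, 1.8)
        trans[f:nt, 1] <- trans[f:nt, 1] + jump
      }
    }
    motion <- cbind(trans, rot)
    colnames(motion) <- c("trans_x", "trans_y", "trans_z",
                          "rot_x", "rot_y", "rot_z")
    k <- config$n_noise_rois
    tt <- seq_len(nt) * config$tr_seconds
    drift <- cbind(tt / max(tt), (tt / max(tt))^2)
    resp <- sin(2 * pi * 0.3 * tt + stats::runif(1, 0, 2 * pi))
    card <- sin(2 * pi * 1.1 * tt + stats::runif(1, 0, 2 * pi))
    noise <- sapply(seq_len(k), function(m) {
      drift %*% stats::rnorm(2, sd = 1.5) +
        stats::rnorm(1, 0.8, 0.2) * resp +
        stats::rnorm(1, 0.5, 0.2) * card +
        stats::rnorm(nt, sd = 0.5)
    })
    half <- ceiling(k / 2)
    colnames(noise) <- c(paste0("wm", seq_len(half)),
                         paste0("csf", seq_len(k - half)))
    list(motion = motion, noise_rois = noise, outlier_truth = spikes)
  })
}

#' Per-subject affect-change covariates of a cohort
#'
#' The single source of the per-subject `dPA`/`dNA` draws: the same values
#' drive the covariate-coupled connectivity shifts in [simulate_cohort()]
#' and the per-subject PANAS total shifts in [simulate_panas_cohort()], so
#' the planted brain-behaviour association survives an end-to-end run.
#'
#' @param config A [cohort_config()].
#' @return data.frame with `subject`, `dPA`, `dNA`.
#' @export
cohort_covariates <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  n <- config$n_subjects
  withr::with_seed(stream_seed(config$seed, 0L, "pre", 2L), {
    data.frame(
      subject = sprintf("s%02d", seq_len(n)),
      dPA = stats::rnorm(n, config$pa_shift_mean, config$pa_shift_sd),
      dNA = stats::rnorm(n, config$na_shift_mean, config$na_shift_sd))
  })
}

#' Simulate a pre/post resting-state cohort
#'
#' Draws, for every subject and condition, a multivariate-normal ROI x time
#' series whose target correlation matrix is block-constant over networks
#' (within- vs between-network levels), with condition and covariate
#' effects injected on the Fisher-z scale (see [cohort_config()]). Subject
#' covariates `dPA` and `dNA` (post-minus-pre PANAS totals) are drawn from
#' the configured normal distributions. Motion, noise-ROI signals, noise
#' leakage and global spike artifacts come from
#' [simulate_motion_and_noise()]. Identical seeds give identical cohorts.
#'
#' @param config A [cohort_config()].
#' @return List with `series` (list of `roi_timeseries`, two per subject,
#'   named `s<NN>_pre` / `s<NN>_post`), `covariates` (data.frame `subject`,
#'   `dPA`, `dNA`) and the `config`.
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  atlas <- config$atlas
  n <- config$n_subjects
  nt <- config$n_volumes
  r_base <- base_correlation_matrix(config)
  ch_base <- chol_or_fail(r_base, config)

  covariates <- cohort_covariates(config)

  series <- list()
  for (s in seq_len(n)) {
    for (cond in c("pre", "post")) {
      shifts <- data.frame(roi_i = character(0), roi_j = character(0),
                           dz = numeric(0))
      if (cond == "post") {
        if (!is.null(config$planted_edges)) {
          pe <- config$planted_edges
          shifts <- rbind(shifts, data.frame(roi_i = pe$roi_i,
                                             roi_j = pe$roi_j,
                                             dz = pe$delta_z))
        }
        if (!is.null(config$covariate_coupling)) {
          cc <- config$covariate_coupling
          centred <- ifelse(cc$covariate == "dPA",
                            covariates$dPA[s] - config$pa_shift_mean,
                            covariates$dNA[s] - config$na_shift_mean)
          shifts <- rbind(shifts, data.frame(roi_i = cc$roi_i,
                                             roi_j = cc$roi_j,
                                             dz = cc$beta * centred))
        }
      }
      ch <- if (nrow(shifts) == 0L) ch_base else {
        chol_or_fail(shifted_correlation(r_base, shifts, atlas), config)
      }
      mn <- simulate_motion_and_noise(config, s, cond)
      data <- withr::with_seed(stream_seed(config$seed, s, cond, 3L), {
        e <- matrix(stats::rnorm(nt * atlas$n_roi), nt, atlas$n_roi)
        x <- e %*% ch
        if (config$noise_leak > 0) {
          w <- matrix(stats::rnorm(ncol(mn$noise_rois) * atlas$n_roi,
                                   sd = config$noise_leak),
                      ncol(mn$noise_rois), atlas$n_roi)
          x <- x + scale(mn$noise_rois) %*% w
        }
        if (any(mn$outlier_truth)) {
          amp <- stats::rnorm(sum(mn$outlier_truth),
                              sd = config$spike_artifact_sd)
          x[mn$outlier_truth, ] <- x[mn$outlier_truth, ] + amp
        }
        x
      })
      colnames(data) <- atlas$roi_names
      obj <- list(subject_id = covariates$subject[s], condition = cond,
                  data = data, motion = mn$motion,
                  noise_rois = mn$noise_rois,
                  outlier_flags = mn$outlier_truth,
                  tr_seconds = config$tr_seconds)
      class(obj) <- "roi_timeseries"
      series[[paste0(covariates$subject[s], "_", cond)]] <- obj
    }
  }
  list(series = series, covariates = covariates, config = config)
}

#' @export
print.roi_timeseries <- function(x, ...) {
  cat("ROI time series:", x$subject_id, "/", x$condition, "-",
      nrow(x$data), "volumes x", ncol(x$data), "ROIs;",
      sum(x$outlier_flags), "flagged frames\n")
  invisible(x)
}

## ---- PANAS item machinery -------------------------------------------------

#' PANAS item names by subscale
#'
#' The standard 10 positive-affect and 10 negative-affect items of the
#' 20-item schedule, each rated 1-5.
#' @return Named list with `pa` and `na` character vectors.
#' @export
panas_items <- function() {
  list(pa = c("interested", "excited", "strong", "enthusiastic", "proud",
              "alert", "inspired", "determined", "attentive", "active"),
       na = c("distressed", "upset", "guilty", "scared", "hostile",
              "irritable", "ashamed", "nervous", "jittery", "afraid"))
}

## Equal-width latent thresholds for the 5-point ordinal response.
panas_thresholds <- c(-1.5, -0.5, 0.5, 1.5)

## Expected ordinal score for latent mean mu (latent sd fixed at 1).
expected_item_score <- function(mu) {
  1 + rowSums(stats::pnorm(outer(mu, panas_thresholds, "-")))
}

## Invert expected_item_score; targets clamped to the attainable range.
latent_mean_for <- function(target) {
  target <- pmin(pmax(target, 1.001), 4.999)
  vapply(target, function(tg) {
    stats::uniroot(function(mu) expected_item_score(mu) - tg,
                   interval = c(-9, 9), tol = 1e-8)$root
  }, numeric(1))
}

## Items whose post-condition latent means shift (by sign of the subscale).
panas_shifted_items <- function() {
  list(pa_up = c("active", "alert", "attentive", "inspired", "proud"),
       na_down = c("nervous", "distressed"))
}

## Allocate a subscale total shift across items: the primary (shifted)
## items absorb it equally up to the expected-score floor/ceiling; any
## overflow spills equally onto the remaining items of the subscale, also
## clamped. Returns the new expected scores for all listed items.
allocate_shift <- function(base_e, primary, secondary, total_shift,
                           lo = 1.001, hi = 4.999) {
  e <- base_e[c(primary, secondary)]
  tgt <- pmin(pmax(e[primary] + total_shift / length(primary), lo), hi)
  leftover <- total_shift - sum(tgt - e[primary])
  e[primary] <- tgt
  if (abs(leftover) > 1e-9 && length(secondary)) {
    e[secondary] <- pmin(pmax(e[secondary] + leftover / length(secondary),
                              lo), hi)
  }
  e
}

## Pre-condition expected item scores: PA items uniform at 29.28/10; the
## two NA items that later drop start elevated (3.5) so a -4.66 total drop
## stays above the per-item floor of 1; remaining NA items share the rest
## of the 16.75 pre-condition total.
panas_baseline_expected <- function() {
  it <- panas_items()
  sh <- panas_shifted_items()
  e <- stats::setNames(numeric(20), c(it$pa, it$na))
  e[it$pa] <- 29.28 / 10
  e[sh$na_down] <- 3.5
  rest <- setdiff(it$na, sh$na_down)
  e[rest] <- (16.75 - sum(e[sh$na_down])) / length(rest)
  e
}

#' Simulate a PANAS cohort with planted affect shifts
#'
#' Ordinal 1-5 item responses are produced by thresholding latent normals
#' (equal-width thresholds, latent SD 1). Each subject draws a target
#' positive-affect total change from `N(pa_shift_mean, pa_shift_sd)` and a
#' negative change from `N(na_shift_mean, na_shift_sd)`; the post-condition
#' latent means of the shifted items (active, alert, attentive, inspired,
#' proud up; nervous, distressed down) are solved numerically so the
#' expected subscale totals move by exactly those amounts; when a shifted
#' item saturates at the 1/5 floor or ceiling the remainder spills onto
#' the other items of the same subscale. Pre-condition expected totals
#' emulate typical pre-intervention levels (PA ~29.3, NA ~16.8). The
#' per-subject shifts are the shared [cohort_covariates()] draws, tying
#' the questionnaire to any covariate-coupled connectivity effects.
#'
#' @param config A [cohort_config()].
#' @return List of `panas_record` objects (two per subject), each with
#'   `subject_id`, `condition` and `items` (named integer vector, 20 items
#'   in 1..5).
#' @export
simulate_panas_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  it <- panas_items()
  sh <- panas_shifted_items()
  base_e <- panas_baseline_expected()
  base_mu <- latent_mean_for(base_e)
  n <- config$n_subjects
  covs <- cohort_covariates(config)
  withr::with_seed(stream_seed(config$seed, 0L, "pre", 4L), {
    records <- list()
    for (s in seq_len(n)) {
      sid <- sprintf("s%02d", s)
      u <- stats::rnorm(1, 0, config$panas_subject_sd)
      post_e <- base_e
      pa_e <- allocate_shift(base_e, sh$pa_up, setdiff(it$pa, sh$pa_up),
                             covs$dPA[s])
      na_e <- allocate_shift(base_e, sh$na_down,
                             setdiff(it$na, sh$na_down), covs$dNA[s])
      post_e[names(pa_e)] <- pa_e
      post_e[names(na_e)] <- na_e
      post_mu <- latent_mean_for(post_e)
      for (cond in c("pre", "post")) {
        mu <- if (cond == "pre") base_mu else post_mu
        latent <- stats::rnorm(20, mu + u, 1)
        score <- 1L + colSums(outer(panas_thresholds, latent, "<"))
        items <- stats::setNames(as.integer(score), names(base_e))
        rec <- list(subject_id = sid, condition = cond, items = items)
        class(rec) <- "panas_record"
        records[[paste0(sid, "_", cond)]] <- rec
      }
    }
    records
  })
}

#' Simulate cardio-respiratory and temperature traces
#'
#' Per subject: a seated baseline followed by an immersion segment with a
#' step increase in heart rate (`hr_step_mean`) and tidal volume
#' (`tidal_step_mean`) and a single large inspiratory gasp within the first
#' seconds of immersion. Heart rate is sampled at 1 Hz, breaths as discrete
#' events (time, inspired volume), and water temperature at 0.1 Hz from
#' `N(water_temp_mean, water_temp_sd)`.
#'
#' @param config A [cohort_config()].
#' @return List of per-subject lists: `hr` (data.frame `time`, `value`),
#'   `breaths` (data.frame `time`, `volume`), `temperature` (data.frame
#'   `time`, `value`), `immersion_start` (s), `trace_end` (s).
#' @export
simulate_physiology <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  bl <- config$baseline_seconds
  im <- config$immersion_seconds
  withr::with_seed(stream_seed(config$seed, 0L, "pre", 5L), {
    lapply(seq_len(config$n_subjects), function(s) {
      hr_base <- stats::rnorm(1, 70, 8)
      hr_step <- stats::rnorm(1, config$hr_step_mean, 1)
      tt <- seq(0, bl + im - 1)
      hr <- hr_base + ifelse(tt >= bl, hr_step, 0) + stats::rnorm(length(tt), sd = 2)
      bt_pre <- seq(2, bl - 2, by = 4)
      bt_post <- seq(bl + 0.5, bl + im, by = 2.4)
      vol_pre <- stats::rnorm(length(bt_pre), 0.5, 0.05)
      vol_post <- stats::rnorm(length(bt_post), 0.5 + config$tidal_step_mean,
                               0.08)
      gasp_t <- bl + stats::runif(1, 1, 6)
      gasp_v <- stats::rnorm(1, config$gasp_volume_mean, 0.2)
      breaths <- data.frame(time = c(bt_pre, gasp_t, bt_post),
                            volume = c(vol_pre, gasp_v, vol_post))
      breaths <- breaths[order(breaths$time), ]
      temp_t <- seq(0, bl + im, by = 10)
      list(subject_id = sprintf("s%02d", s),
           hr = data.frame(time = tt, value = hr),
           breaths = breaths,
           temperature = data.frame(
             time = temp_t,
             value = stats::rnorm(length(temp_t), config$water_temp_mean,
                                  config$water_temp_sd)),
           immersion_start = bl, trace_end = bl + im)
    })
  })
}
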