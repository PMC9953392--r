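#' Framewise displacement from 6 motion parameters
#'
#' Power-style FD: the sum of absolute frame-to-frame differences of the
#' three translations (mm) and the three rotations converted to arc length
#' on a 50 mm sphere. The first frame has FD 0 by convention.
#'
#' @param motion T x 6 matrix: 3 translations (mm), 3 rotations (rad).
#' @param radius_mm Sphere radius for the rotation term (default 50).
#' @return Numeric vector of length T.
#' @export
framewise_displacement <- function(motion, radius_mm = 50) {
  motion <- as.matrix(motion)
  if (ncol(motion) != 6) stop("motion must have 6 columns")
  d <- abs(diff(motion))
  fd <- rowSums(d[, 1:3, drop = FALSE]) +
    radius_mm * rowSums(d[, 4:6, drop = FALSE])
  c(0, fd)
}

#' Flag outlier frames from motion and global signal
#'
#' A frame is flagged when its framewise displacement exceeds `fd_thresh`
#' (default 0.9 mm) or the frame-to-frame change in the global signal
#' exceeds `gs_sd` standard deviations (default 5) of that change.
#'
#' @param motion T x 6 motion-parameter matrix.
#' @param global_signal Length-T global (mean) BOLD signal.
#' @param fd_thresh FD threshold in mm (default 0.9).
#' @param gs_sd Global-signal-change threshold in SD units (default 5).
#' @return Logical vector of length T.
#' @export
flag_outliers <- function(motion, global_signal, fd_thresh = 0.9,
                          gs_sd = 5) {
  motion <- as.matrix(motion)
  if (nrow(motion) != length(global_signal)) {
    stop("motion rows (", nrow(motion), ") != global signal length (",
         length(global_signal), ")")
  }
  fd <- framewise_displacement(motion)
  dg <- c(0, diff(global_signal))
  s <- stats::sd(dg)
  gs_flag <- if (is.finite(s) && s > 0) abs(dg) > gs_sd * s else
    rep(FALSE, length(dg))
  fd > fd_thresh | gs_flag
}

#' Principal-component nuisance regressors from noise-ROI signals
#'
#' aCompCor-style components: the noise-ROI matrix is linearly detrended
#' column-wise and its top `k` principal-component time courses are
#' returned, scaled to unit variance. When column names mark separate
#' masks (`wm*` / `csf*`) `k` components are extracted per mask.
#'
#' @param noise_rois T x m matrix of surrogate noise signals.
#' @param k Components per mask (default 5). `k = 0` gives a zero-column
#'   matrix.
#' @param per_mask Split columns into masks by name prefix (default TRUE).
#' @return T x (k * n_masks) matrix of unit-variance, mutually orthogonal
#'   component time courses.
#' @export
compcor_components <- function(noise_rois, k = 5, per_mask = TRUE) {
  noise_rois <- as.matrix(noise_rois)
  nt <- nrow(noise_rois)
  if (k == 0) return(matrix(0, nt, 0))
  masks <- if (per_mask && !is.null(colnames(noise_rois))) {
    prefix <- sub("[0-9]+$", "", colnames(noise_rois))
    split(seq_len(ncol(noise_rois)), prefix)
  } else list(all = seq_len(ncol(noise_rois)))
  comps <- lapply(names(masks), function(m) {
    x <- noise_rois[, masks[[m]], drop = FALSE]
    tt <- seq_len(nt)
    x <- apply(x, 2, function(col) stats::resid(stats::lm.fit(
      cbind(1, tt), col)))
    pc <- stats::prcomp(x, center = TRUE, scale. = FALSE)
    kk <- min(k, ncol(pc$x))
    if (kk < k) warning("mask '", m, "' has rank ", kk, " < k = ", k)
    sc <- pc$x[, seq_len(kk), drop = FALSE]
    sc <- scale(sc)
    colnames(sc) <- paste0(m, "_pc", seq_len(kk))
    sc
  })
  do.call(cbind, comps)
}

#' Assemble the nuisance design for one session
#'
#' Twelve motion regressors (6 parameters + their first differences),
#' aCompCor components, and one indicator column per flagged frame.
#'
#' @param series A `roi_timeseries`.
#' @param k Components per noise mask (default 5).
#' @param flags Optional logical outlier flags; default
#'   [flag_outliers()] on the series' own motion and global signal.
#' @return List of class `confound_set`: `motion12`, `compcor`,
#'   `outlier_regressors`, `flags`.
#' @export
build_confounds <- function(series, k = 5, flags = NULL) {
  stopifnot(inherits(series, "roi_timeseries"))
  motion <- series$motion
  motion12 <- cbind(motion, rbind(0, diff(motion)))
  colnames(motion12) <- c(colnames(motion), paste0("d_", colnames(motion)))
  comp <- compcor_components(series$noise_rois, k = k)
  if (is.null(flags)) {
    flags <- flag_outliers(motion, rowMeans(series$data))
  }
  out_reg <- matrix(0, nrow(series$data), sum(flags))
  if (sum(flags)) {
    out_reg[cbind(which(flags), seq_len(sum(flags)))] <- 1
    colnames(out_reg) <- paste0("outlier_", which(flags))
  }
  out <- list(motion12 = motion12, compcor = comp,
              outlier_regressors = out_reg, flags = flags)
  class(out) <- "confound_set"
  out
}

#' Regress confounds out of a multichannel series
#'
#' Ordinary least squares of every column of `series` on an intercept plus
#' the confound columns; returns the residuals. Collinear confound columns
#' are dropped with a warning.
#'
#' @param series T x p numeric matrix.
#' @param confounds T x q numeric matrix (or `confound_set`, in which case
#'   `motion12` and `compcor` are used).
#' @return T x p residual matrix (orthogonal to every retained confound).
#' @export
regress_confounds <- function(series, confounds) {
  series <- as.matrix(series)
  if (inherits(confounds, "confound_set")) {
    confounds <- cbind(confounds$motion12, confounds$compcor)
  }
  confounds <- as.matrix(confounds)
  if (nrow(confounds) != nrow(series)) {
    stop("confound rows (", nrow(confounds), ") != series rows (",
         nrow(series), ")")
  }
  x <- cbind(intercept = 1, confounds)
  qx <- qr(x)
  if (qx$rank < ncol(x)) {
    drop_idx <- qx$pivot[-seq_len(qx$rank)]
    warning("dropping ", length(drop_idx), " collinear confound column(s): ",
            paste(colnames(x)[drop_idx], collapse = ", "))
    x <- x[, qx$pivot[seq_len(qx$rank)], drop = FALSE]
    qx <- qr(x)
  }
  resid <- series - x %*% qr.coef(qx, series)
  dimnames(resid) <- dimnames(series)
  resid
}

#' Ideal band-pass filter
#'
#' Zero-phase frequency-domain filter: the discrete Fourier transform is
#' masked to retain components with frequency in `[low, high]` Hz
#' (inclusive) and inverted. The DC component is always removed.
#'
#' @param series T x p matrix (or vector) sampled every `tr` seconds.
#' @param tr Sampling interval in seconds.
#' @param low,high Pass band in Hz (defaults 0.008 and 0.09).
#' @return Filtered series, same shape as the input.
#' @export
bandpass <- function(series, tr, low = 0.008, high = 0.09) {
  stopifnot(tr > 0, low < high)
  nyquist <- 1 / (2 * tr)
  if (high > nyquist) {
    stop("upper band edge ", high, " Hz exceeds the Nyquist frequency ",
         signif(nyquist, 4), " Hz")
  }
  x <- as.matrix(series)
  nt <- nrow(x)
  freq <- (seq_len(nt) - 1) / (nt * tr)
  folded <- pmin(freq, 1 / tr - freq)
  mask <- folded >= low & folded <= high
  out <- apply(x, 2, function(col) {
    Re(stats::fft(stats::fft(col) * mask, inverse = TRUE)) / nt
  })
  out <- matrix(out, nrow = nt, dimnames = dimnames(x))
  if (is.vector(series)) drop(out) else out
}

#' Censor flagged frames
#'
#' Removes flagged frames from a series (order preserved), the scrubbing
#' step applied after filtering and before correlation.
#'
#' @param series T x p matrix (or vector).
#' @param flags Logical vector of length T.
#' @return The series without flagged rows.
#' @export
censor_frames <- function(series, flags) {
  x <- as.matrix(series)
  if (length(flags) != nrow(x)) stop("flags not aligned with series")
  if (all(flags)) stop("all frames flagged; nothing left to analyse")
  out <- x[!flags, , drop = FALSE]
  if (is.vector(series)) drop(out) else out
}

#' Denoise one session
#'
#' Fixed pipeline: band-pass the motion/aCompCor confounds, regress them
#' from the data, band-pass the residuals, then censor flagged frames.
#' Band-passing the confounds before regression keeps regression and
#' filtering from reintroducing each other's removed variance, which makes
#' the regress-then-filter pair idempotent (up to DC).
#'
#' @param series A `roi_timeseries`.
#' @param k aCompCor components per mask (default 5).
#' @param low,high Pass band in Hz (defaults 0.008, 0.09).
#' @param censor Remove flagged frames at the end (default TRUE).
#' @return A `roi_timeseries` with denoised `data` (and matching `motion`,
#'   `noise_rois`, `outlier_flags` if censored).
#' @export
denoise_series <- function(series, k = 5, low = 0.008, high = 0.09,
                           censor = TRUE) {
  stopifnot(inherits(series, "roi_timeseries"))
  conf <- build_confounds(series, k = k)
  nuis <- cbind(conf$motion12, conf$compcor)
  nuis_bp <- bandpass(nuis, series$tr_seconds, low, high)
  resid <- regress_confounds(series$data, nuis_bp)
  resid <- bandpass(resid, series$tr_seconds, low, high)
  out <- series
  out$data <- resid
  if (censor && any(conf$flags)) {
    out$data <- censor_frames(out$data, conf$flags)
    out$motion <- out$motion[!conf$flags, , drop = FALSE]
    out$noise_rois <- out$noise_rois[!conf$flags, , drop = FALSE]
    out$outlier_flags <- conf$flags[!conf$flags]
  }
  attr(out$data, "flags") <- conf$flags
  out
}

#' QC-FC: association between connectivity and subject motion
#'
#' Correlates, across subjects, each edge's connectivity with the
#' subject's mean framewise displacement, and tests whether the resulting
#' edge-wise correlation distribution is centred on zero with a sign-flip
#' permutation of the (centred) motion summaries.
#'
#' @param fc_matrices List (length n >= 5) of symmetric ROI x ROI
#'   connectivity matrices, one per subject.
#' @param motion_summaries Numeric vector of per-subject mean FD.
#' @param n_perm Sign-flip permutations (default 1000).
#' @param seed RNG seed (default 1).
#' @return List: `edge_correlations`, `median`, `iqr`, `statistic`
#'   (median), `p` (two-sided sign-flip p for "centred on zero").
#' @export
qc_fc <- function(fc_matrices, motion_summaries, n_perm = 1000, seed = 1) {
  n <- length(fc_matrices)
  if (n < 5) stop("need >= 5 subjects for QC-FC")
  stopifnot(length(motion_summaries) == n)
  ut <- upper.tri(fc_matrices[[1]])
  fc <- t(vapply(fc_matrices, function(m) m[ut],
                 numeric(sum(ut))))
  keep <- apply(fc, 2, stats::sd) > 0
  fc <- fc[, keep, drop = FALSE]
  if (stats::sd(motion_summaries) == 0) {
    stop("motion summaries have zero variance")
  }
  obs <- as.numeric(stats::cor(fc, motion_summaries))
  med <- stats::median(obs)
  centred <- motion_summaries - mean(motion_summaries)
  null <- withr::with_seed(seed, {
    vapply(seq_len(n_perm), function(b) {
      s <- sample(c(-1, 1), n, replace = TRUE)
      stats::median(as.numeric(stats::cor(fc, centred * s)))
    }, numeric(1))
  })
  list(edge_correlations = obs, median = med,
       iqr = stats::IQR(obs), statistic = med,
       p = mean(abs(null) >= abs(med)))
}
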