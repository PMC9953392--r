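#' Weighted Pearson correlation
#'
#' Pearson correlation with non-negative temporal weights applied to the
#' means, variances and covariance. Uniform weights reduce exactly to the
#' ordinary Pearson correlation.
#'
#' @param x,y Numeric vectors of equal length.
#' @param weights Non-negative weights, not all zero (default uniform).
#' @return Correlation in `[-1, 1]`.
#' @export
weighted_correlation <- function(x, y, weights = rep(1, length(x))) {
  stopifnot(length(x) == length(y), length(weights) == length(x))
  if (any(weights < 0) || sum(weights) == 0) {
    stop("weights must be non-negative and not all zero")
  }
  w <- weights / sum(weights)
  mx <- sum(w * x); my <- sum(w * y)
  vx <- sum(w * (x - mx)^2); vy <- sum(w * (y - my)^2)
  if (vx == 0 || vy == 0) stop("zero weighted variance")
  sxy <- sum(w * (x - mx) * (y - my))
  max(-1, min(1, sxy / sqrt(vx * vy)))
}

#' Fisher z transform and its inverse
#'
#' `fisher_z(r) = atanh(r)`, the variance-stabilising transform of a
#' correlation; `inverse_fisher(z) = tanh(z)`.
#'
#' @param r Correlation(s) with `|r| < 1`.
#' @param z Fisher z value(s).
#' @return Transformed values.
#' @examples
#' fisher_z(0.5)  # 0.549306 = log(3)/2
#' @export
fisher_z <- function(r) {
  if (any(abs(r) >= 1)) stop("|r| must be < 1 for the Fisher transform")
  atanh(r)
}

#' @rdname fisher_z
#' @export
inverse_fisher <- function(z) tanh(z)

## Weighted correlation matrix over the columns of x.
weighted_cor_matrix <- function(x, weights = rep(1, nrow(x))) {
  w <- weights / sum(weights)
  mu <- colSums(w * x)
  xc <- sweep(x, 2, mu)
  cv <- crossprod(xc * w, xc)
  s <- sqrt(diag(cv))
  if (any(s == 0)) stop("zero-variance ROI series")
  r <- cv / tcrossprod(s)
  r[r > 1] <- 1; r[r < -1] <- -1
  r
}

#' Build per-subject, per-condition Fisher-z connectivity matrices
#'
#' Weighted ROI-to-ROI Pearson correlations per session, clamped at
#' `|r| = 1 - 1e-12` and Fisher transformed. Default weights are uniform
#' over the session. Subjects lacking either condition are excluded with a
#' message. Degenerate (duplicated) ROI pairs produce the maximal finite z
#' and are counted in the `clamped` attribute.
#'
#' @param series List of `roi_timeseries` (e.g. `simulate_cohort()$series`,
#'   possibly after [denoise_series()]).
#' @param weights Optional list of per-session weight vectors (matched by
#'   name) or a single function `function(n_frames)` returning weights.
#' @return List of `connectivity_matrix` objects: `subject_id`,
#'   `condition`, `z` (symmetric ROI x ROI, zero diagonal).
#' @export
build_rrc <- function(series, weights = NULL) {
  ids <- vapply(series, function(s) s$subject_id, character(1))
  conds <- vapply(series, function(s) s$condition, character(1))
  complete <- intersect(ids[conds == "pre"], ids[conds == "post"])
  excluded <- setdiff(unique(ids), complete)
  if (length(excluded)) {
    message("excluding subject(s) without both conditions: ",
            paste(excluded, collapse = ", "))
  }
  keep <- which(ids %in% complete)
  out <- lapply(keep, function(k) {
    s <- series[[k]]
    w <- if (is.null(weights)) rep(1, nrow(s$data))
    else if (is.function(weights)) weights(nrow(s$data))
    else weights[[names(series)[k]]]
    r <- weighted_cor_matrix(s$data, w)
    diag(r) <- 0
    clamp <- abs(r) >= 1 - 1e-12
    r[clamp] <- sign(r[clamp]) * (1 - 1e-12)
    z <- atanh(r)
    diag(z) <- 0
    m <- list(subject_id = s$subject_id, condition = s$condition, z = z)
    attr(m, "clamped") <- sum(clamp) / 2
    class(m) <- "connectivity_matrix"
    m
  })
  names(out) <- names(series)[keep]
  out
}

#' @export
print.connectivity_matrix <- function(x, ...) {
  cat("Fisher-z connectivity:", x$subject_id, "/", x$condition, "-",
      nrow(x$z), "x", ncol(x$z), "\n")
  invisible(x)
}
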