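#' Second-level design over edge differences
#'
#' Builds, from paired pre/post Fisher-z matrices, the per-subject edge
#' response (z_post - z_pre for every unique undirected edge) and the
#' design matrix of an edge-wise GLM. The design always contains an
#' intercept; affect-change covariates (e.g. `dPA = PA_post - PA_pre`,
#' `dNA`) are appended in the order given by `columns`.
#'
#' @param matrices List of `connectivity_matrix` from [build_rrc()].
#' @param atlas The `nbs_atlas` the matrices were computed on.
#' @param covariates Optional data.frame with a `subject` column plus
#'   numeric covariate columns.
#' @param columns Character vector of covariate columns to enter the
#'   design (default none: intercept-only).
#' @return Object of class `nbs_design`: `D` (n_subjects x n_edges matrix
#'   of z differences), `X` (design matrix), `edges` (edge index from
#'   [list_edges()]), `subjects`, `atlas`.
#' @export
build_design <- function(matrices, atlas, covariates = NULL,
                         columns = character(0)) {
  stopifnot(inherits(atlas, "nbs_atlas"))
  ids <- vapply(matrices, function(m) m$subject_id, character(1))
  conds <- vapply(matrices, function(m) m$condition, character(1))
  subjects <- sort(intersect(ids[conds == "pre"], ids[conds == "post"]))
  if (length(subjects) < 2) stop("need >= 2 subjects with both conditions")
  edges <- list_edges(atlas)
  eidx <- cbind(edges$pairs$i, edges$pairs$j)
  D <- t(vapply(subjects, function(s) {
    zpre <- matrices[[which(ids == s & conds == "pre")[1]]]$z
    zpost <- matrices[[which(ids == s & conds == "post")[1]]]$z
    (zpost - zpre)[eidx]
  }, numeric(nrow(eidx))))
  X <- matrix(1, length(subjects), 1, dimnames = list(subjects, "intercept"))
  if (length(columns)) {
    stopifnot(!is.null(covariates), "subject" %in% names(covariates),
              all(columns %in% names(covariates)))
    rows <- match(subjects, covariates$subject)
    if (anyNA(rows)) {
      stop("covariates missing for subject(s): ",
           paste(subjects[is.na(rows)], collapse = ", "))
    }
    X <- cbind(X, as.matrix(covariates[rows, columns, drop = FALSE]))
    colnames(X) <- c("intercept", columns)
  }
  out <- list(D = D, X = X, edges = edges, subjects = subjects,
              atlas = atlas)
  class(out) <- "nbs_design"
  out
}

## Vectorised edge-wise GLM t statistics for contrast cvec.
glm_tstats <- function(D, X, cvec, se_floor = 1e-12) {
  n <- nrow(X)
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    stop("collinear design columns: ",
         paste(colnames(X)[qx$pivot[-seq_len(qx$rank)]], collapse = ", "))
  }
  xtx_inv <- chol2inv(qr.R(qx))
  beta <- xtx_inv %*% crossprod(X, D)
  resid <- D - X %*% beta
  df <- n - qx$rank
  sigma2 <- colSums(resid^2) / df
  cb <- as.numeric(crossprod(cvec, beta))
  cvar <- as.numeric(crossprod(cvec, xtx_inv %*% cvec))
  se <- sqrt(pmax(sigma2 * cvar, 0))
  clamped <- se < se_floor
  se[clamped] <- se_floor
  list(T = cb / se, df = df, clamped = clamped)
}

normalise_contrast <- function(design, contrast) {
  cols <- colnames(design$X)
  if (is.null(names(contrast))) {
    stopifnot(length(contrast) == length(cols))
    return(as.numeric(contrast))
  }
  unknown <- setdiff(names(contrast), cols)
  if (length(unknown)) stop("contrast names not in design: ",
                            paste(unknown, collapse = ", "))
  cv <- stats::setNames(numeric(length(cols)), cols)
  cv[names(contrast)] <- contrast
  as.numeric(cv)
}

#' Edge-wise general linear model
#'
#' Least-squares fit of every edge's pre/post z difference on the design,
#' with `T = c'beta / se(c'beta)` and two-sided p from Student's t with
#' `df = n - rank(design)`. Edges with (near) zero residual variance get a
#' standard-error floor of 1e-12 and are flagged `clamped`.
#'
#' @param design An `nbs_design` from [build_design()].
#' @param contrast Named (or full-length) numeric contrast over the design
#'   columns; default the intercept (condition effect).
#' @return data.frame of class `edge_stats`: `i`, `j`, `roi_i`, `roi_j`,
#'   `T`, `df`, `p`, `clamped`.
#' @export
edge_glm <- function(design, contrast = c(intercept = 1)) {
  stopifnot(inherits(design, "nbs_design"))
  cvec <- normalise_contrast(design, contrast)
  res <- glm_tstats(design$D, design$X, cvec)
  if (any(res$clamped)) {
    warning(sum(res$clamped),
            " edge(s) with ~zero residual variance; T clamped via se floor")
  }
  out <- design$edges$pairs
  out$T <- res$T
  out$df <- res$df
  out$p <- 2 * stats::pt(-abs(res$T), res$df)
  out$clamped <- res$clamped
  class(out) <- c("edge_stats", class(out))
  attr(out, "contrast") <- cvec
  out
}

#' Select suprathreshold edges
#'
#' Retains edges with two-sided `p < p_height`; the sign of T is kept so
#' positive and negative couplings remain distinguishable.
#'
#' @param stats An `edge_stats` data.frame from [edge_glm()].
#' @param p_height Uncorrected height (connection) threshold in (0, 1].
#' @return Subset of `stats`.
#' @export
threshold_edges <- function(stats, p_height) {
  stopifnot(p_height > 0, p_height <= 1)
  if (p_height == 1) return(stats)
  stats[stats$p < p_height, , drop = FALSE]
}

#' Connected components of a suprathreshold edge set
#'
#' Components of the undirected graph whose vertices are atlas ROIs and
#' whose edges are the suprathreshold connections; each component carries
#' its edge list with signed T values, its size (edge count), mass
#' (sum of squared T) and intensity (sum of absolute T).
#'
#' @param edges data.frame with `roi_i`, `roi_j` and optionally `T`.
#' @param atlas The `nbs_atlas`.
#' @return List of `nbs_component` objects.
#' @export
find_components <- function(edges, atlas) {
  stopifnot(inherits(atlas, "nbs_atlas"))
  if (nrow(edges) == 0L) return(list())
  roi_index(atlas, edges$roi_i); roi_index(atlas, edges$roi_j)
  if (is.null(edges$T)) edges$T <- NA_real_
  g <- igraph::graph_from_data_frame(
    edges[, c("roi_i", "roi_j")], directed = FALSE,
    vertices = data.frame(name = atlas$roi_names))
  memb <- igraph::components(g)$membership
  comp_of_edge <- memb[edges$roi_i]
  lapply(unique(comp_of_edge), function(cid) {
    e <- edges[comp_of_edge == cid, , drop = FALSE]
    comp <- list(edges = e[, c("roi_i", "roi_j", "T")],
                 rois = sort(unique(c(e$roi_i, e$roi_j))),
                 size = nrow(e),
                 mass = sum(e$T^2),
                 intensity = sum(abs(e$T)))
    class(comp) <- "nbs_component"
    comp
  })
}

#' Component mass statistic
#'
#' The mass of a component is the sum of squared edge T statistics; the
#' secondary intensity measure is the sum of absolute T values. Accepts
#' either an `nbs_component` or a bare numeric vector of T statistics.
#'
#' @param component An `nbs_component`, or numeric T values.
#' @return The mass (sum of T squared).
#' @examples
#' component_mass(c(5.70, 6.64, 3.75, -8.64))  # 165.29
#' @export
component_mass <- function(component) {
  tv <- if (inherits(component, "nbs_component")) component$edges$T
  else as.numeric(component)
  sum(tv^2)
}

#' Component intensity statistic (sum of absolute T)
#' @inheritParams component_mass
#' @return The intensity.
#' @export
component_intensity <- function(component) {
  tv <- if (inherits(component, "nbs_component")) component$edges$T
  else as.numeric(component)
  sum(abs(tv))
}

## Max component mass among suprathreshold edges, via integer union-find.
max_component_mass <- function(idx, tvals, ei, ej) {
  if (length(idx) == 0L) return(0)
  if (length(idx) == 1L) return(tvals[idx]^2)
  nodes <- unique(c(ei[idx], ej[idx]))
  a <- match(ei[idx], nodes)
  b <- match(ej[idx], nodes)
  parent <- seq_along(nodes)
  find <- function(v) {
    while (parent[v] != v) {
      parent[v] <<- parent[parent[v]]
      v <- parent[v]
    }
    v
  }
  mass <- numeric(length(nodes))
  for (k in seq_along(idx)) {
    ra <- find(a[k]); rb <- find(b[k])
    if (ra != rb) {
      parent[rb] <- ra
      mass[ra] <- mass[ra] + mass[rb]
      mass[rb] <- 0
    }
    mass[ra] <- mass[ra] + tvals[idx[k]]^2
  }
  max(mass)
}

#' Permutation null distribution of the maximum component mass
#'
#' For the condition (intercept) contrast each permutation flips the sign
#' of every subject's edge-difference row independently; for covariate
#' contrasts a single random permutation of the covariate rows is applied
#' identically across all edges, preserving the dependence between edges
#' within a subject. Each permutation reruns the edge GLM, thresholds at
#' `p_height`, forms components and records the largest mass (0 when no
#' edge survives).
#'
#' @param design An `nbs_design`.
#' @param contrast Contrast vector (named or full length).
#' @param p_height Height threshold (default 0.001).
#' @param n_perm Number of permutations, >= 100 (default 1000).
#' @param seed RNG seed.
#' @param scheme `"auto"` (sign flips iff the contrast loads only on the
#'   intercept), `"sign_flip"` or `"covariate"`.
#' @return List of class `permutation_null`: `max_mass` (length n_perm),
#'   `scheme`, `n_perm`, `seed`, `p_height`.
#' @export
permutation_null <- function(design, contrast = c(intercept = 1),
                             p_height = 0.001, n_perm = 1000, seed = 1,
                             scheme = c("auto", "sign_flip", "covariate")) {
  stopifnot(inherits(design, "nbs_design"))
  if (n_perm < 100) stop("n_perm must be >= 100 for a stable null tail")
  scheme <- match.arg(scheme)
  cvec <- normalise_contrast(design, contrast)
  if (scheme == "auto") {
    scheme <- if (all(cvec[-1] == 0)) "sign_flip" else "covariate"
  }
  D <- design$D; X <- design$X
  n <- nrow(X)
  df <- n - qr(X)$rank
  tcrit <- stats::qt(1 - p_height / 2, df)
  ei <- design$edges$pairs$i; ej <- design$edges$pairs$j
  max_mass <- withr::with_seed(seed, {
    vapply(seq_len(n_perm), function(b) {
      if (scheme == "sign_flip") {
        s <- sample(c(-1, 1), n, replace = TRUE)
        tv <- glm_tstats(D * s, X, cvec)$T
      } else {
        pr <- sample.int(n)
        Xp <- X
        Xp[, -1] <- X[pr, -1, drop = FALSE]
        tv <- glm_tstats(D, Xp, cvec)$T
      }
      max_component_mass(which(abs(tv) > tcrit), tv, ei, ej)
    }, numeric(1))
  })
  out <- list(max_mass = max_mass, scheme = scheme, n_perm = n_perm,
              seed = seed, p_height = p_height)
  class(out) <- "permutation_null"
  out
}

#' Family-wise error p-value of an observed component mass
#'
#' Proportion of permutations whose largest component mass is at least the
#' observed mass (ties count). The add-one smoothed variant
#' `(1 + #) / (n_perm + 1)` is available by flag.
#'
#' @param observed_mass Observed component mass.
#' @param null A `permutation_null`.
#' @param smoothed Use the add-one estimator (default FALSE).
#' @return p in `[0, 1]`.
#' @export
fwe_pvalue <- function(observed_mass, null, smoothed = FALSE) {
  stopifnot(inherits(null, "permutation_null"))
  hits <- sum(null$max_mass >= observed_mass)
  if (smoothed) (1 + hits) / (null$n_perm + 1) else hits / null$n_perm
}

#' Run the full network-based statistic
#'
#' Edge-wise GLM, height thresholding, component formation, and
#' permutation FWE p-values for every observed component (each compared to
#' the null distribution of the maximum component mass).
#'
#' @inheritParams permutation_null
#' @param alpha Component-level significance level (default 0.05).
#' @return List of class `nbs_result`: `components` (each with `p_fwe` and
#'   `significant`), `stats` (edge GLM table), `null`, `p_height`,
#'   `contrast`.
#' @export
run_nbs <- function(design, contrast = c(intercept = 1), p_height = 0.001,
                    n_perm = 1000, seed = 1, alpha = 0.05,
                    scheme = c("auto", "sign_flip", "covariate")) {
  scheme <- match.arg(scheme)
  stats_tab <- edge_glm(design, contrast)
  supra <- threshold_edges(stats_tab, p_height)
  comps <- find_components(supra, design$atlas)
  null <- permutation_null(design, contrast, p_height, n_perm, seed,
                           scheme)
  comps <- lapply(comps, function(cp) {
    cp$p_fwe <- fwe_pvalue(cp$mass, null)
    cp$significant <- cp$p_fwe < alpha
    cp
  })
  if (length(comps)) {
    comps <- comps[order(vapply(comps, function(cp) -cp$mass, numeric(1)))]
  }
  out <- list(components = comps, stats = stats_tab, null = null,
              p_height = p_height,
              contrast = normalise_contrast(design, contrast),
              alpha = alpha, n_subjects = length(design$subjects))
  class(out) <- "nbs_result"
  out
}

#' @export
print.nbs_result <- function(x, ...) {
  cat(sprintf("NBS: %d subject(s), height p < %g, %d permutation(s) [%s]\n",
              x$n_subjects, x$p_height, x$null$n_perm, x$null$scheme))
  if (!length(x$components)) {
    cat("no suprathreshold components\n")
    return(invisible(x))
  }
  for (cp in x$components) {
    cat(sprintf("  component: size = %d, mass = %.2f, intensity = %.2f, p-FWE = %.4g%s\n",
                cp$size, cp$mass, cp$intensity, cp$p_fwe,
                if (cp$significant) " *" else ""))
  }
  invisible(x)
}

#' Sweep the cluster-forming threshold
#'
#' Reruns the NBS over a grid of height thresholds and classifies each
#' family of overlapping significant components: `"focal"` if significant
#' only at conservative thresholds (<= 0.001), `"distributed"` if only at
#' liberal ones (>= 0.01), `"mixed"` if at both. Components at different
#' thresholds belong to the same family when they share at least one edge.
#'
#' @inheritParams run_nbs
#' @param thresholds Decreasing vector of height thresholds (default
#'   0.05-0.01 by 0.01, then 0.001 and 0.0001).
#' @return List of class `sweep_result`: `by_threshold` (named list of
#'   `nbs_result`), `families` (data.frame with `family`,
#'   `classification`, `n_edges`, `thresholds`), `thresholds`.
#' @export
threshold_sweep <- function(design, contrast = c(intercept = 1),
                            thresholds = c(seq(0.05, 0.01, by = -0.01),
                                           0.001, 0.0001),
                            n_perm = 1000, seed = 1, alpha = 0.05) {
  stopifnot(length(thresholds) >= 2)
  thresholds <- sort(unique(thresholds), decreasing = TRUE)
  results <- lapply(seq_along(thresholds), function(k) {
    run_nbs(design, contrast, p_height = thresholds[k], n_perm = n_perm,
            seed = seed + k, alpha = alpha)
  })
  names(results) <- paste0("p", thresholds)

  sig <- list()
  for (k in seq_along(thresholds)) {
    for (cp in results[[k]]$components) {
      if (cp$significant) {
        sig[[length(sig) + 1]] <- list(threshold = thresholds[k],
                                       comp = cp)
      }
    }
  }
  families <- data.frame(family = integer(0), classification = character(0),
                         n_edges = integer(0), thresholds = character(0))
  if (length(sig)) {
    edge_key <- function(cp) {
      paste(pmin(cp$edges$roi_i, cp$edges$roi_j),
            pmax(cp$edges$roi_i, cp$edges$roi_j), sep = "--")
    }
    m <- length(sig)
    fam <- seq_len(m)
    for (a in seq_len(m - 1)) {
      for (b in seq(a + 1, m)) {
        if (length(intersect(edge_key(sig[[a]]$comp),
                             edge_key(sig[[b]]$comp)))) {
          fam[fam == fam[b]] <- fam[a]
        }
      }
    }
    families <- do.call(rbind, lapply(unique(fam), function(f) {
      members <- sig[fam == f]
      thr <- vapply(members, function(s) s$threshold, numeric(1))
      cons <- any(thr <= 0.001); lib <- any(thr >= 0.01)
      data.frame(
        family = f,
        classification = if (cons && lib) "mixed"
        else if (cons) "focal" else "distributed",
        n_edges = length(unique(unlist(lapply(members,
                                              function(s) edge_key(s$comp))))),
        thresholds = paste(sort(unique(thr), decreasing = TRUE),
                           collapse = ","))
    }))
  }
  out <- list(by_threshold = results, families = families,
              thresholds = thresholds)
  class(out) <- "sweep_result"
  out
}

#' Per-edge effect size with confidence interval
#'
#' For a covariate contrast: the Pearson correlation between the covariate
#' and the edge's z difference, with a Fisher-z CI (default 90%). For the
#' condition (intercept) contrast: the standardized mean difference
#' `mean / sd` of the edge differences with a noncentral-t CI. An interval
#' covering zero flags the edge as not reliably estimable at that
#' confidence level.
#'
#' @param diffs Per-subject edge z differences (n >= 5).
#' @param covariate Optional covariate vector; omit for the condition
#'   contrast.
#' @param conf Confidence level (default 0.90).
#' @return List: `type` (`"correlation"` or `"smd"`), `estimate`, `ci`,
#'   `conf`, `reliable` (CI excludes 0), `n`.
#' @export
edge_effect_size <- function(diffs, covariate = NULL, conf = 0.90) {
  diffs <- as.numeric(diffs)
  n <- length(diffs)
  if (n < 5) stop("need n >= 5")
  if (stats::sd(diffs) == 0) stop("zero variance in edge differences")
  if (!is.null(covariate)) {
    stopifnot(length(covariate) == n)
    if (stats::sd(covariate) == 0) stop("zero variance in covariate")
    r <- stats::cor(diffs, covariate)
    if (abs(r) >= 1) {
      ci <- c(r, r)
    } else {
      zse <- stats::qnorm(1 - (1 - conf) / 2) / sqrt(n - 3)
      ci <- tanh(atanh(r) + c(-zse, zse))
    }
    est <- r; type <- "correlation"
  } else {
    est <- mean(diffs) / stats::sd(diffs)
    tt <- est * sqrt(n)
    ci <- unname(cohen_d_ci(tt, n, conf))
    type <- "smd"
  }
  list(type = type, estimate = est, ci = ci, conf = conf,
       reliable = ci[1] > 0 || ci[2] < 0, n = n)
}
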