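# A tiny hand-built design around known edge differences.
toy_design <- function(D, X = NULL, atlas = atlas30) {
  n <- nrow(D)
  if (is.null(X)) {
    X <- matrix(1, n, 1, dimnames = list(NULL, "intercept"))
  }
  edges <- list_edges(atlas)
  stopifnot(ncol(D) == edges$n_unique)
  d <- list(D = D, X = X, edges = edges,
            subjects = sprintf("s%02d", seq_len(n)), atlas = atlas)
  class(d) <- "nbs_design"
  d
}

test_that("edge GLM reproduces the one-sample t on hand data", {
  D <- matrix(0, 3, 435)
  D[, 1] <- c(1, 2, 3)
  d <- toy_design(D)
  s <- suppressWarnings(edge_glm(d))
  expect_equal(s$T[1], 3.464, tolerance = 1e-3)
  expect_equal(s$df[1], 2)
  # all-zero edges: T = 0 with the se floor, p = 1
  expect_equal(s$T[2], 0)
  expect_equal(s$p[2], 1)
  expect_true(s$clamped[2])
})

test_that("a perfect covariate fit is clamped with a warning", {
  set.seed(71)
  n <- 10
  dpa <- rnorm(n, 7, 2.5)
  D <- matrix(rnorm(n * 435, sd = 0.1), n, 435)
  D[, 5] <- 0.1 * dpa  # exact linear dependence, zero residual
  X <- cbind(intercept = 1, dPA = dpa)
  d <- toy_design(D, X)
  expect_warning(s <- edge_glm(d, c(dPA = 1)), "clamped")
  expect_true(s$clamped[5])
  expect_gt(abs(s$T[5]), 1e6)
})

test_that("height thresholding retains edges beyond the critical t", {
  D <- matrix(rnorm(31 * 435, sd = 0.05), 31, 435)
  d <- toy_design(D)
  s <- edge_glm(d)
  expect_equal(s$df[1], 30)
  tcrit <- qt(1 - 0.001 / 2, 30)
  expect_equal(tcrit, 3.646, tolerance = 1e-3)
  kept <- threshold_edges(s, 0.001)
  expect_true(all(abs(kept$T) > tcrit))
  expect_equal(nrow(threshold_edges(s, 1)), 435)

  # a T of 3.75 at df 30 survives p < 0.001, mirroring the worked cluster
  expect_lt(2 * pt(-3.75, 30), 0.001)
})

test_that("connected components follow the suprathreshold topology", {
  star <- data.frame(
    roi_i = rep("DMN.MPFC", 4),
    roi_j = c("SN.AIns-L", "SN.RPFC-L", "DMN.LP-L", "SN.ACC"),
    T = c(5.70, 6.64, 3.75, -8.64))
  comps <- find_components(star, atlas30)
  expect_equal(length(comps), 1)
  expect_equal(comps[[1]]$size, 4)
  expect_equal(comps[[1]]$mass, sum(star$T^2))

  disjoint <- data.frame(roi_i = c("DMN.MPFC", "Vis.Medial"),
                         roi_j = c("DMN.PCC", "Vis.Occipital"),
                         T = c(2, 3))
  expect_equal(length(find_components(disjoint, atlas30)), 2)

  chain <- data.frame(roi_i = c("DMN.MPFC", "DMN.PCC"),
                      roi_j = c("DMN.PCC", "DMN.LP-L"), T = c(2, 2))
  cc <- find_components(chain, atlas30)
  expect_equal(length(cc), 1)
  expect_equal(cc[[1]]$size, 2)

  expect_equal(length(find_components(star[0, ], atlas30)), 0)
})

test_that("component mass and intensity match their definitions", {
  expect_equal(component_mass(c(5.70, 6.64, 3.75, -8.64)), 165.2917,
               tolerance = 1e-6)
  expect_equal(component_mass(c(7.59, 8.31)), 126.6642, tolerance = 1e-6)
  expect_equal(component_mass(2), 4)
  expect_equal(component_intensity(c(-3, 4)), 7)
  # single-edge component: mass = T^2 exactly
  single <- find_components(
    data.frame(roi_i = "DMN.MPFC", roi_j = "DMN.PCC", T = 12.43),
    atlas30)
  expect_equal(single[[1]]$mass, 12.43^2)
})

test_that("FWE p-value conventions count ties and support smoothing", {
  null <- list(max_mass = c(0, 1, 2, 3, 4, 5, 6, 7, 8, 9), n_perm = 10,
               scheme = "sign_flip", seed = 1, p_height = 0.01)
  class(null) <- "permutation_null"
  expect_equal(fwe_pvalue(100, null), 0)
  expect_equal(fwe_pvalue(100, null, smoothed = TRUE), 1 / 11)
  expect_equal(fwe_pvalue(0, null), 1)   # ties count ("same or greater")
  expect_equal(fwe_pvalue(5, null), 0.5)
})

test_that("permutation null is reproducible and scheme-aware", {
  co <- simulate_cohort(clean_config(n_subjects = 8, n_volumes = 80,
                                     seed = 72))
  d <- build_design(build_rrc(co$series), atlas30, co$covariates,
                    c("dPA", "dNA"))
  n1 <- permutation_null(d, c(intercept = 1), 0.01, 150, seed = 5)
  n2 <- permutation_null(d, c(intercept = 1), 0.01, 150, seed = 5)
  expect_identical(n1$max_mass, n2$max_mass)
  expect_equal(n1$scheme, "sign_flip")
  n3 <- permutation_null(d, c(dPA = 1), 0.01, 150, seed = 5)
  expect_equal(n3$scheme, "covariate")
  expect_error(permutation_null(d, c(intercept = 1), 0.01, 50), "100")
})

test_that("Monte-Carlo FWE p matches the exhaustive sign-flip oracle", {
  cc <- clean_config(
    n_subjects = 6, n_volumes = 100, seed = 42,
    planted_edges = data.frame(roi_i = "DMN.MPFC", roi_j = "SN.ACC",
                               delta_z = 0.35))
  co <- simulate_cohort(cc)
  d <- build_design(build_rrc(co$series), atlas30)
  p_h <- 0.05
  s <- edge_glm(d)
  comps <- find_components(threshold_edges(s, p_h), atlas30)
  obs <- max(vapply(comps, function(cp) cp$mass, numeric(1)))

  # exhaustive oracle over all 2^6 sign patterns, written independently
  D <- d$D
  n <- 6
  tcrit <- qt(1 - p_h / 2, n - 1)
  ei <- d$edges$pairs$i; ej <- d$edges$pairs$j
  all_mass <- vapply(0:63, function(bits) {
    sgn <- ifelse(bitwAnd(bits, 2^(0:5)) > 0, -1, 1)
    Dp <- D * sgn
    tv <- colMeans(Dp) / (apply(Dp, 2, sd) / sqrt(n))
    idx <- which(abs(tv) > tcrit)
    if (!length(idx)) return(0)
    g <- igraph::graph_from_edgelist(cbind(ei[idx], ej[idx]),
                                     directed = FALSE)
    memb <- igraph::components(g)$membership
    max(tapply(tv[idx]^2, memb[ei[idx]], sum))
  }, numeric(1))
  p_exhaustive <- mean(all_mass >= obs)

  null <- permutation_null(d, c(intercept = 1), p_height = p_h,
                           n_perm = 800, seed = 7)
  expect_lt(abs(fwe_pvalue(obs, null) - p_exhaustive), 0.02)
})

test_that("component mass is non-increasing as the threshold tightens", {
  co <- simulate_cohort(clean_config(
    n_subjects = 10, n_volumes = 120, seed = 73,
    planted_edges = data.frame(roi_i = "DMN.MPFC", roi_j = "SN.ACC",
                               delta_z = 0.5)))
  d <- build_design(build_rrc(co$series), atlas30)
  s <- edge_glm(d)
  masses <- vapply(c(0.05, 0.01, 0.001), function(ph) {
    comps <- find_components(threshold_edges(s, ph), atlas30)
    if (!length(comps)) 0 else max(vapply(comps, function(cp) cp$mass,
                                          numeric(1)))
  }, numeric(1))
  expect_true(all(diff(masses) <= 1e-12))
})

test_that("FWE p is invariant to relabelling the atlas ROIs", {
  co <- simulate_cohort(clean_config(n_subjects = 8, n_volumes = 90,
                                     seed = 74))
  m <- build_rrc(co$series)
  d <- build_design(m, atlas30)
  r1 <- run_nbs(d, p_height = 0.01, n_perm = 150, seed = 9)

  # permute ROI order consistently in atlas and matrices
  set.seed(75)
  perm <- sample(30)
  a2 <- list(roi_names = atlas30$roi_names[perm],
             network_of = atlas30$network_of[perm], n_roi = 30L)
  class(a2) <- "nbs_atlas"
  m2 <- lapply(m, function(x) {
    x$z <- x$z[perm, perm]
    x
  })
  d2 <- build_design(m2, a2)
  r2 <- run_nbs(d2, p_height = 0.01, n_perm = 150, seed = 9)
  p1 <- sort(vapply(r1$components, function(cp) cp$p_fwe, numeric(1)))
  p2 <- sort(vapply(r2$components, function(cp) cp$p_fwe, numeric(1)))
  m1 <- sort(vapply(r1$components, function(cp) cp$mass, numeric(1)))
  m2s <- sort(vapply(r2$components, function(cp) cp$mass, numeric(1)))
  expect_equal(m1, m2s, tolerance = 1e-10)
  expect_equal(p1, p2)
})

test_that("a covariate-driven effect disappears without its covariate", {
  planted <- planted_star(t_target = 6, n_subjects = 16, n_volumes = 240)
  cc <- clean_config(n_subjects = 16, n_volumes = 240, seed = 76,
                     covariate_coupling = planted)
  co <- simulate_cohort(cc)
  m <- build_rrc(co$series)
  key <- edge_keys(planted)

  d_cov <- build_design(m, atlas30, co$covariates, "dPA")
  r_cov <- run_nbs(d_cov, c(dPA = 1), p_height = 0.001, n_perm = 200,
                   seed = 11)
  hit_cov <- any(vapply(r_cov$components, function(cp)
    cp$significant && length(intersect(edge_keys(cp$edges), key)) > 0,
    logical(1)))
  expect_true(hit_cov)

  d_int <- build_design(m, atlas30)
  r_int <- run_nbs(d_int, p_height = 0.001, n_perm = 200, seed = 11)
  hit_int <- any(vapply(r_int$components, function(cp)
    cp$significant && length(intersect(edge_keys(cp$edges), key)) > 0,
    logical(1)))
  expect_false(hit_int)
})

test_that("threshold sweep classifies focal versus distributed effects", {
  # strong focal pair: two planted edges with large condition deltas
  cc <- clean_config(
    n_subjects = 16, n_volumes = 200, seed = 77,
    planted_edges = data.frame(
      roi_i = c("FP.PPC-R", "FP.PPC-R"),
      roi_j = c("DAN.IPS-R", "Vis.Lateral-R"),
      delta_z = c(0.45, 0.45)))
  co <- simulate_cohort(cc)
  d <- build_design(build_rrc(co$series), atlas30)
  sw <- threshold_sweep(d, thresholds = c(0.05, 0.01, 0.001),
                        n_perm = 150, seed = 13)
  expect_s3_class(sw, "sweep_result")
  expect_gt(nrow(sw$families), 0)
  expect_true(all(sw$families$classification %in%
                    c("focal", "mixed", "distributed")))
  # a strong planted effect must not be distributed-only
  expect_true(any(sw$families$classification %in% c("focal", "mixed")))

  # null data: no significant families
  co0 <- simulate_cohort(clean_config(n_subjects = 10, n_volumes = 100,
                                      seed = 78))
  d0 <- build_design(build_rrc(co0$series), atlas30)
  sw0 <- threshold_sweep(d0, thresholds = c(0.01, 0.001), n_perm = 150,
                         seed = 14)
  expect_equal(nrow(sw0$families), 0)
})

test_that("edge effect sizes carry interval coverage and reliability flags", {
  x <- c(1, 2, 3, 4, 5, 6)
  out <- edge_effect_size(x, covariate = x)
  expect_equal(out$estimate, 1)
  expect_true(out$reliable)

  set.seed(79)
  cover <- vapply(1:60, function(k) {
    d <- rnorm(31); cv <- rnorm(31)
    es <- edge_effect_size(d, cv)
    es$ci[1] <= 0 && es$ci[2] >= 0
  }, logical(1))
  expect_gt(mean(cover), 0.80)  # 90% nominal, binomial noise over 60

  es0 <- edge_effect_size(rnorm(31), rnorm(31))
  expect_type(es0$reliable, "logical")
  smd <- edge_effect_size(rnorm(20, 1))
  expect_equal(smd$type, "smd")
  expect_error(edge_effect_size(rep(1, 10), rnorm(10)), "variance")
  expect_error(edge_effect_size(1:3), "n >= 5")
})
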