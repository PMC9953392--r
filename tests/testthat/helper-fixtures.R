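# Shared fixtures: small, fast cohort configurations built in code.

atlas30 <- build_default_atlas()

# Clean config: no noise leakage or motion spikes, so correlation structure
# is exactly the planted multivariate-normal one.
clean_config <- function(n_subjects = 8, n_volumes = 100, seed = 1, ...) {
  cohort_config(n_subjects = n_subjects, n_volumes = n_volumes,
                motion_spike_rate = 0, noise_leak = 0, seed = seed, ...)
}

# The 4-edge star planted around the medial prefrontal node, covariate
# coupled to dPA with beta calibrated for a target per-edge |T| at the
# given cohort size (from the Fisher-z sampling variance 1/(T-3) per
# session, 2/(T-3) for the pre/post difference).
planted_star <- function(t_target = 5, n_subjects = 31, n_volumes = 292,
                         sd_cov = 2.5) {
  beta <- t_target * sqrt(2 / (n_volumes - 3)) /
    (sd_cov * sqrt(n_subjects))
  data.frame(
    roi_i = rep("DMN.MPFC", 4),
    roi_j = c("SN.AIns-L", "SN.RPFC-L", "DMN.LP-L", "SN.ACC"),
    beta = c(1, 1, 1, -1) * beta,
    covariate = "dPA")
}

edge_keys <- function(df) {
  paste(pmin(df$roi_i, df$roi_j), pmax(df$roi_i, df$roi_j), sep = "--")
}

# Synthetic PANAS record with constant item values.
flat_record <- function(value, subject = "s01", condition = "pre") {
  rec <- list(subject_id = subject, condition = condition,
              items = stats::setNames(rep(as.integer(value), 20),
                                      unlist(panas_items(),
                                             use.names = FALSE)))
  class(rec) <- "panas_record"
  rec
}
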