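## Plain-text serialisation: one TSV per subject/condition for the BOLD
## series (columns = ROI labels), sidecar TSVs for motion and noise ROIs,
## a PANAS CSV, a covariate CSV and a JSON manifest.

#' Write a simulated cohort to a directory of TSV/CSV files
#'
#' @param cohort Result of [simulate_cohort()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the manifest path.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (nm in names(cohort$series)) {
    s <- cohort$series[[nm]]
    utils::write.table(s$data, file.path(dir, paste0(nm, "_bold.tsv")),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    utils::write.table(s$motion, file.path(dir, paste0(nm, "_motion.tsv")),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    utils::write.table(s$noise_rois,
                       file.path(dir, paste0(nm, "_noise.tsv")),
                       sep = "\t", row.names = FALSE, quote = FALSE)
  }
  utils::write.csv(cohort$covariates, file.path(dir, "covariates.csv"),
                   row.names = FALSE)
  cfg <- cohort$config
  cfg$atlas <- NULL
  cfg <- cfg[!vapply(cfg, is.null, logical(1))]
  manifest <- file.path(dir, "manifest.json")
  jsonlite::write_json(cfg, manifest, auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}

#' Read one subject/condition ROI time series from TSV files
#'
#' @param dir Directory written by [write_cohort()].
#' @param subject_id Subject label, e.g. `"s01"`.
#' @param condition `"pre"` or `"post"`.
#' @param tr_seconds Repetition time of the stored series.
#' @return A `roi_timeseries`.
#' @export
read_roi_tsv <- function(dir, subject_id, condition, tr_seconds = 2.68) {
  stem <- file.path(dir, paste0(subject_id, "_", condition))
  for (suffix in c("_bold.tsv", "_motion.tsv", "_noise.tsv")) {
    f <- paste0(stem, suffix)
    if (!file.exists(f)) stop("missing file: ", f)
  }
  data <- as.matrix(utils::read.delim(paste0(stem, "_bold.tsv"),
                                      check.names = FALSE))
  motion <- as.matrix(utils::read.delim(paste0(stem, "_motion.tsv")))
  noise <- as.matrix(utils::read.delim(paste0(stem, "_noise.tsv")))
  obj <- list(subject_id = subject_id, condition = condition, data = data,
              motion = motion, noise_rois = noise,
              outlier_flags = rep(FALSE, nrow(data)),
              tr_seconds = tr_seconds)
  class(obj) <- "roi_timeseries"
  obj
}

#' Read per-subject covariates (dPA, dNA) from CSV
#' @param path CSV with columns `subject`, `dPA`, `dNA`.
#' @return data.frame.
#' @export
read_covariates_csv <- function(path) {
  if (!file.exists(path)) stop("missing covariate file: ", path)
  cov <- utils::read.csv(path)
  stopifnot(all(c("subject", "dPA", "dNA") %in% names(cov)))
  cov
}

#' Write PANAS records to CSV
#' @param records List of `panas_record`.
#' @param path Output CSV path (columns: subject, condition, 20 items).
#' @return Invisibly, `path`.
#' @export
write_panas_csv <- function(records, path) {
  tab <- do.call(rbind, lapply(records, function(r) {
    data.frame(subject = r$subject_id, condition = r$condition,
               t(r$items), check.names = FALSE)
  }))
  utils::write.csv(tab, path, row.names = FALSE)
  invisible(path)
}

#' Read PANAS records from CSV
#' @param path CSV written by [write_panas_csv()] (or in the same layout).
#' @return List of `panas_record`.
#' @export
read_panas_csv <- function(path) {
  if (!file.exists(path)) stop("missing PANAS file: ", path)
  tab <- utils::read.csv(path, check.names = FALSE)
  it <- unlist(panas_items(), use.names = FALSE)
  missing <- setdiff(it, names(tab))
  if (length(missing)) stop("PANAS CSV lacks item column(s): ",
                            paste(missing, collapse = ", "))
  recs <- lapply(seq_len(nrow(tab)), function(k) {
    rec <- list(subject_id = tab$subject[k], condition = tab$condition[k],
                items = stats::setNames(as.integer(tab[k, it]), it))
    class(rec) <- "panas_record"
    rec
  })
  names(recs) <- paste0(tab$subject, "_", tab$condition)
  recs
}

#' Write a component report as JSON with a TSV twin
#'
#' One entry per component: edges (ROI labels plus network names), size,
#' mass, intensity and FWE p. The TSV twin (same path with `.tsv`) holds
#' one row per edge for spreadsheet use.
#'
#' @param components List of `nbs_component` (with `p_fwe`), e.g.
#'   `run_nbs()$components`.
#' @param path Output JSON path.
#' @param atlas Atlas used for network lookup (default
#'   [build_default_atlas()]).
#' @return Invisibly, `path`.
#' @export
write_component_report <- function(components, path,
                                   atlas = build_default_atlas()) {
  report <- lapply(components, function(cp) {
    list(size = cp$size, mass = cp$mass, intensity = cp$intensity,
         p_fwe = if (is.null(cp$p_fwe)) NA else cp$p_fwe,
         edges = lapply(seq_len(nrow(cp$edges)), function(k) {
           list(roi_i = cp$edges$roi_i[k],
                network_i = unname(atlas$network_of[cp$edges$roi_i[k]]),
                roi_j = cp$edges$roi_j[k],
                network_j = unname(atlas$network_of[cp$edges$roi_j[k]]),
                T = cp$edges$T[k])
         }))
  })
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA)
  tsv <- sub("\\.json$", ".tsv", path)
  if (tsv == path) tsv <- paste0(path, ".tsv")
  rows <- do.call(rbind, lapply(seq_along(components), function(ci) {
    cp <- components[[ci]]
    data.frame(component = ci, roi_i = cp$edges$roi_i,
               roi_j = cp$edges$roi_j, T = cp$edges$T, size = cp$size,
               mass = cp$mass,
               p_fwe = if (is.null(cp$p_fwe)) NA else cp$p_fwe)
  }))
  if (is.null(rows)) {
    rows <- data.frame(component = integer(0), roi_i = character(0),
                       roi_j = character(0), T = numeric(0),
                       size = integer(0), mass = numeric(0),
                       p_fwe = numeric(0))
  }
  utils::write.table(rows, tsv, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Read back a component report
#' @param path JSON written by [write_component_report()].
#' @return List of component lists.
#' @export
read_component_report <- function(path) {
  jsonlite::read_json(path, simplifyVector = FALSE)
}
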