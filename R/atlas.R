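#' Default 30-ROI large-scale network atlas
#'
#' Builds the cortical atlas used throughout the package: 30 regions of
#' interest assigned to 7 canonical large-scale networks (default mode,
#' sensorimotor, visual, salience/cingulo-opercular, dorsal attention,
#' frontoparietal and language). Cerebellar nodes are deliberately absent.
#' With 30 nodes the edge set comprises 435 unique undirected connections
#' (870 ordered pairs).
#'
#' @return An object of class `nbs_atlas`: a list with `roi_names`
#'   (character vector of 30 unique labels), `network_of` (named character
#'   vector mapping each ROI to its network) and `n_roi`.
#' @examples
#' atlas <- build_default_atlas()
#' atlas$n_roi
#' table(atlas$network_of)
#' @export
build_default_atlas <- function() {
  nets <- list(
    DMN            = c("MPFC", "PCC", "LP-L", "LP-R"),
    SensoriMotor   = c("Lateral-L", "Lateral-R", "Superior"),
    Visual         = c("Medial", "Occipital", "Lateral-L", "Lateral-R"),
    Salience       = c("ACC", "AIns-L", "AIns-R", "RPFC-L", "RPFC-R",
                       "SMG-L", "SMG-R"),
    DorsalAttention = c("FEF-L", "FEF-R", "IPS-L", "IPS-R"),
    FrontoParietal = c("LPFC-L", "LPFC-R", "PPC-L", "PPC-R"),
    Language       = c("IFG-L", "IFG-R", "pSTS-L", "pSTS-R")
  )
  abbrev <- c(DMN = "DMN", SensoriMotor = "SM", Visual = "Vis",
              Salience = "SN", DorsalAttention = "DAN",
              FrontoParietal = "FP", Language = "Lang")
  roi_names <- unlist(lapply(names(nets), function(nw) {
    paste0(abbrev[[nw]], ".", nets[[nw]])
  }), use.names = FALSE)
  network_of <- stats::setNames(
    rep(names(nets), vapply(nets, length, integer(1))), roi_names)
  atlas <- list(roi_names = roi_names, network_of = network_of,
                n_roi = length(roi_names))
  class(atlas) <- "nbs_atlas"
  stopifnot(!anyDuplicated(atlas$roi_names))
  atlas
}

#' @export
print.nbs_atlas <- function(x, ...) {
  cat("ROI atlas:", x$n_roi, "ROIs in",
      length(unique(x$network_of)), "networks\n")
  print(table(x$network_of))
  invisible(x)
}

#' Enumerate the edges of an atlas
#'
#' Lists the unique undirected ROI pairs of an atlas. Inference is run once
#' per unique edge; the ordered-pair count (twice the unique count) is
#' reported alongside because symmetric connectivity matrices are often
#' described by their ordered connection count.
#'
#' @param atlas An `nbs_atlas`, e.g. from [build_default_atlas()].
#' @return A list with `pairs` (data.frame of `i`, `j` integer indices with
#'   `i < j`, plus `roi_i`, `roi_j` labels), `n_unique` and `n_ordered`.
#' @examples
#' e <- list_edges(build_default_atlas())
#' e$n_ordered  # 870
#' e$n_unique   # 435
#' @export
list_edges <- function(atlas) {
  stopifnot(inherits(atlas, "nbs_atlas"))
  n <- atlas$n_roi
  idx <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  ord <- order(idx[, "row"], idx[, "col"])
  pairs <- data.frame(i = idx[ord, "row"], j = idx[ord, "col"])
  pairs$roi_i <- atlas$roi_names[pairs$i]
  pairs$roi_j <- atlas$roi_names[pairs$j]
  list(pairs = pairs, n_unique = n * (n - 1L) / 2L, n_ordered = n * (n - 1L))
}

#' Look up atlas ROI indices by label
#' @param atlas An `nbs_atlas`.
#' @param labels Character vector of ROI labels.
#' @return Integer indices into `atlas$roi_names`.
#' @keywords internal
roi_index <- function(atlas, labels) {
  idx <- match(labels, atlas$roi_names)
  if (anyNA(idx)) {
    stop("unknown ROI label(s): ",
         paste(labels[is.na(idx)], collapse = ", "))
  }
  idx
}
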