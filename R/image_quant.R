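#' Segment nuclei from a nuclear-stain channel
#'
#' A fixed, standard operator chain: global Otsu threshold on the
#' intensity-normalized channel, hole filling, 8-connected component
#' labeling, and removal of components smaller than `min_area` pixels,
#' with surviving components relabeled 1..K in scan order. A constant
#' image yields an empty label map (zero nuclei), not an error.
#'
#' @param nuclear Numeric matrix of nuclear-stain intensities.
#' @param min_area Minimum nucleus area in pixels; default 50.
#' @return Integer label matrix (0 = background, k = nucleus k) of class
#'   `nucleus_labels` with attribute `n_nuclei`.
#' @export
segment_nuclei <- function(nuclear, min_area = 50) {
  nuclear <- as.matrix(nuclear)
  if (length(nuclear) == 0L) stop("empty image", call. = FALSE)
  stop_if_not_scalar_count(min_area, "min_area", min = 1)
  rng <- range(nuclear)
  if (diff(rng) == 0) {
    lab <- matrix(0L, nrow(nuclear), ncol(nuclear))
    return(structure(lab, n_nuclei = 0L, class = "nucleus_labels"))
  }
  norm <- (nuclear - rng[[1]]) / diff(rng)
  thr <- EBImage::otsu(EBImage::Image(norm), range = c(0, 1))
  mask <- norm > thr
  mask <- EBImage::fillHull(EBImage::Image(mask)) > 0
  lab <- .label_components8(matrix(as.logical(mask), nrow(nuclear)))
  sizes <- tabulate(lab[lab > 0])
  keep <- which(sizes >= min_area)
  remap <- integer(length(sizes))
  remap[keep] <- seq_along(keep)
  lab[lab > 0] <- remap[lab[lab > 0]]
  structure(lab, n_nuclei = length(keep), class = "nucleus_labels")
}

#' @export
print.nucleus_labels <- function(x, ...) {
  cat(sprintf("nucleus_labels: %d x %d pixels, %d nuclei\n",
              nrow(x), ncol(x), attr(x, "n_nuclei")))
  invisible(x)
}

#' Per-nucleus integrated density of a protein channel
#'
#' For each labeled nucleus, sums the protein-channel intensities over the
#' nucleus' pixels (the raw integrated density; no background subtraction
#' unless `subtract_background` is set, in which case the median intensity
#' outside all nuclei is subtracted per pixel).
#'
#' @param labels A [segment_nuclei()] label map (or integer matrix).
#' @param protein Numeric matrix of protein-channel intensities, same
#'   shape.
#' @param subtract_background Subtract the median background intensity per
#'   pixel before summing; default FALSE.
#' @return Data frame with `label`, `area`, `integrated_density`,
#'   `mean_intensity`.
#' @export
integrated_density <- function(labels, protein, subtract_background = FALSE) {
  protein <- as.matrix(protein)
  if (!all(dim(labels) == dim(protein)))
    stop("label map and protein channel must have the same shape",
         call. = FALSE)
  if (subtract_background && any(labels == 0L))
    protein <- protein - median(protein[labels == 0L])
  k <- max(0L, max(labels))
  if (k == 0L)
    return(data.frame(label = integer(0), area = integer(0),
                      integrated_density = numeric(0),
                      mean_intensity = numeric(0)))
  inside <- labels > 0L
  area <- tabulate(labels[inside], nbins = k)
  dens <- vapply(seq_len(k), function(i) sum(protein[labels == i]),
                 numeric(1))
  data.frame(label = seq_len(k), area = area, integrated_density = dens,
             mean_intensity = dens / area)
}

#' Relative integrated density of treated versus control nuclei
#'
#' Normalizes each treated nucleus' integrated density by the mean
#' integrated density of the control nuclei, the dimensionless per-nucleus
#' readout used to compare protein levels across conditions.
#'
#' @param treated,control [integrated_density()] tables (control must be
#'   non-empty with positive mean density).
#' @return The treated table with an added `relative_integrated_density`
#'   column; attribute `control_mean` records the normalizer.
#' @export
relative_integrated_density <- function(treated, control) {
  stopifnot(is.data.frame(treated), is.data.frame(control),
            "integrated_density" %in% names(treated),
            "integrated_density" %in% names(control))
  if (nrow(control) == 0L)
    stop("control measurements are empty", call. = FALSE)
  m <- mean(control$integrated_density)
  if (!is.finite(m) || m <= 0)
    stop("control mean integrated density must be positive", call. = FALSE)
  treated$relative_integrated_density <- treated$integrated_density / m
  attr(treated, "control_mean") <- m
  treated
}

#' Segment and measure nuclei in one call
#'
#' @param nuclear,protein Numeric matrices (nuclear stain, protein channel).
#' @inheritParams segment_nuclei
#' @inheritParams integrated_density
#' @return [integrated_density()] table for the segmented nuclei.
#' @export
quantify_nuclei <- function(nuclear, protein, min_area = 50,
                            subtract_background = FALSE) {
  integrated_density(segment_nuclei(nuclear, min_area), protein,
                     subtract_background)
}
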