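# Whole-tumor histogram feature extraction and two-reader handling.

#' Histogram features of one parameter map
#'
#' Computes the six whole-tumor histogram statistics of a pooled per-voxel
#' value vector: arithmetic mean; 5th, 50th and 95th percentiles by linear
#' interpolation of order statistics (rank `1 + (n-1)q`); population
#' (biased) skewness; and population non-excess kurtosis (a normal
#' distribution gives 3, the attainable lower bound is 1).
#'
#' @param values numeric vector of ROI voxel values; NAs are dropped.
#'   Fewer than 10 valid voxels is an error, fewer than 50 a warning
#'   (percentiles need support).
#' @return named numeric vector: `mean`, `p5`, `p50`, `p95`, `skewness`,
#'   `kurtosis`.
#' @examples
#' extract_features(rnorm(1000))
#' @export
extract_features <- function(values) {
  values <- values[is.finite(values)]
  n <- length(values)
  if (n == 0) stop("no valid voxel values", call. = FALSE)
  if (n < 10) stop("fewer than 10 valid voxels", call. = FALSE)
  if (n < 50) warning("fewer than 50 valid voxels; percentiles are unstable",
                      call. = FALSE)
  q <- stats::quantile(values, c(0.05, 0.5, 0.95), names = FALSE, type = 7)
  m <- mean(values)
  dev <- values - m
  m2 <- mean(dev^2)
  if (m2 <= .Machine$double.eps * max(1, m^2)) {
    warning("zero variance; skewness and kurtosis undefined", call. = FALSE)
    skew <- NaN; kurt <- NaN
  } else {
    skew <- mean(dev^3) / m2^1.5
    kurt <- mean(dev^4) / m2^2
  }
  c(mean = m, p5 = q[1], p50 = q[2], p95 = q[3],
    skewness = skew, kurtosis = kurt)
}

#' Histogram features of all maps of a fitted ROI
#'
#' @param pm a `param_maps` object ([fit_roi()] output).
#' @param mask optional alternative ROI (e.g. a second reader's mask);
#'   defaults to the mask the maps were fitted on. Only voxels carrying a
#'   fitted value contribute.
#' @return one-row data frame with columns `<map>_<feature>`.
#' @export
roi_histogram_features <- function(pm, mask = NULL) {
  stopifnot(inherits(pm, "param_maps"))
  use <- if (is.null(mask)) pm$mask else .validate_mask(mask, dim(pm$mask))
  out <- list()
  for (map in names(pm$maps)) {
    v <- pm$maps[[map]][use]
    feats <- extract_features(v)
    names(feats) <- paste(map, names(feats), sep = "_")
    out[[map]] <- feats
  }
  as.data.frame(as.list(unlist(unname(out))), check.names = FALSE)
}

#' Average the histogram features of two readers
#'
#' Element-wise arithmetic mean of two feature sets for the same subject;
#' features are averaged, not the underlying maps.
#'
#' @param a,b named numeric vectors or one-row data frames with identical
#'   feature names.
#' @return same shape as `a`.
#' @export
average_readers <- function(a, b) {
  na <- if (is.data.frame(a)) names(a) else names(a)
  nb <- if (is.data.frame(b)) names(b) else names(b)
  if (is.null(na) || !identical(sort(na), sort(nb)))
    stop("feature sets of the two readers do not match", call. = FALSE)
  if (is.data.frame(a)) {
    (a[na] + b[na]) / 2
  } else {
    (a[na] + b[na]) / 2
  }
}

# logical 3D neighbour shifts along one axis
.shift3 <- function(m, axis, by) {
  out <- array(FALSE, dim(m))
  d <- dim(m)
  src <- lapply(d, seq_len)
  dst <- src
  if (by == 1) { dst[[axis]] <- 2:d[axis]; src[[axis]] <- 1:(d[axis] - 1) }
  else { dst[[axis]] <- 1:(d[axis] - 1); src[[axis]] <- 2:d[axis] }
  out[dst[[1]], dst[[2]], dst[[3]]] <- m[src[[1]], src[[2]], src[[3]]]
  out
}

.neighbour_count <- function(m) {
  n <- array(0L, dim(m))
  for (axis in 1:3) for (by in c(1, -1)) n <- n + .shift3(m, axis, by)
  n
}

#' Simulate a second reader's ROI
#'
#' Emulates inter-reader delineation variability by seeded random erosion /
#' dilation of the mask boundary: each foreground boundary voxel is removed
#' and each background voxel touching the mask is added independently with
#' probability `jitter` (6-neighbourhood). The default 0.1 keeps the Dice
#' overlap with the original mask above 0.85 for tumor-sized ROIs.
#' `jitter = 0` returns the mask unchanged.
#'
#' @param mask 3D binary array.
#' @param jitter flip probability of boundary voxels in \[0, 1).
#' @param seed integer seed, or NULL.
#' @return perturbed 3D logical mask.
#' @export
simulate_second_reader <- function(mask, jitter = 0.1, seed = NULL) {
  mask <- .validate_mask(mask, min_voxels = 1L)
  if (jitter < 0 || jitter >= 1)
    stop("'jitter' must lie in [0, 1)", call. = FALSE)
  if (jitter == 0) return(mask)
  if (!is.null(seed)) set.seed(seed)
  nb <- .neighbour_count(mask)
  boundary <- mask & nb < 6L
  candidates <- !mask & nb > 0L
  out <- mask
  bi <- which(boundary)
  ci <- which(candidates)
  out[bi] <- stats::runif(length(bi)) >= jitter
  out[ci] <- stats::runif(length(ci)) < jitter
  if (!any(out)) stop("perturbation emptied the mask", call. = FALSE)
  out
}

#' Dice overlap of two binary masks
#'
#' @param a,b 3D binary arrays on the same grid.
#' @return Dice coefficient `2|A n B| / (|A| + |B|)`.
#' @export
dice_overlap <- function(a, b) {
  a <- .validate_mask(a); b <- .validate_mask(b, dim(a))
  2 * sum(a & b) / (sum(a) + sum(b))
}

#' Long-format feature table
#'
#' Reshapes per-reader wide feature tables (columns `<map>_<feature>`)
#' into the tidy layout: one row per subject x reader x map x feature.
#'
#' @param ... one wide data frame per reader, named (e.g.
#'   `reader_a = fa, reader_b = fb`), each with one row per subject.
#' @param subjects optional subject identifiers (default row numbers).
#' @return data frame with columns `subject`, `reader`, `map`, `feature`,
#'   `value`.
#' @export
features_long <- function(..., subjects = NULL) {
  readers <- list(...)
  if (is.null(names(readers)) || any(names(readers) == ""))
    names(readers) <- paste0("reader_", seq_along(readers))
  out <- list()
  for (rd in names(readers)) {
    wide <- as.data.frame(readers[[rd]])
    ids <- if (is.null(subjects)) seq_len(nrow(wide)) else subjects
    keep <- grep("_", names(wide), value = TRUE)
    for (cn in keep) {
      map <- sub("_[^_]+$", "", cn)
      feat <- sub("^.*_", "", cn)
      out[[length(out) + 1L]] <- data.frame(
        subject = ids, reader = rd, map = map, feature = feat,
        value = wide[[cn]])
    }
  }
  do.call(rbind, out)
}
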