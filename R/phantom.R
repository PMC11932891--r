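# Digital phantom: seeded synthetic DWI volumes, ROI masks, ground-truth
# parameter maps and clinical covariates for two Ki-67 expression classes.

#' Per-class parameter distribution specification
#'
#' Describes the per-voxel sampling distributions of the six diffusion
#' parameters for one Ki-67 class, plus the class-conditional probability
#' of an elevated AFP level (>= 20 ng/mL). Positive coefficients (adc, d,
#' d_star, ddc) are drawn log-normally with the stated arithmetic mean;
#' the bounded parameters f and alpha are drawn logit-normally, so physical
#' ranges hold without truncation. A spread quoted as an interquartile
#' range is converted to the normal-equivalent SD (IQR / 1.349).
#'
#' @param location named vector of distribution locations for
#'   `adc, d, d_star, f, ddc, alpha` (coefficients in 10^-3 mm^2/s).
#' @param spread named vector of spreads on the same scale (>= 0).
#' @param spread_type `"sd"` or `"iqr"` per parameter (recycled).
#' @param afp_positive_rate probability of AFP >= 20 ng/mL in this class.
#' @param voxel_cv intra-tumor coefficient of variation used by
#'   [generate_cohort()] when it re-centres the spec on a subject: the
#'   class-level spread is treated as inter-subject and `voxel_cv` sets the
#'   within-tumor spread around the subject location.
#' @param s0 baseline signal level (arbitrary units).
#' @param label free-text class label.
#' @return list of class `"class_distribution_spec"`.
#' @seealso [hcc_high_ki67_spec()], [hcc_low_ki67_spec()]
#' @export
class_distribution_spec <- function(location, spread,
                                    spread_type = "sd",
                                    afp_positive_rate,
                                    voxel_cv = 0.2, s0 = 100,
                                    label = "") {
  pars <- c("adc", "d", "d_star", "f", "ddc", "alpha")
  if (!all(pars %in% names(location)) || !all(pars %in% names(spread)))
    stop("'location' and 'spread' must name all of: ",
         paste(pars, collapse = ", "), call. = FALSE)
  location <- location[pars]; spread <- spread[pars]
  spread_type <- rep_len(spread_type, length(pars))
  if (any(spread < 0)) stop("spreads must be >= 0", call. = FALSE)
  if (any(location[c("adc", "d", "d_star", "ddc")] <= 0))
    stop("coefficient locations must be positive", call. = FALSE)
  if (location[["f"]] < 0 || location[["f"]] > 1 ||
      location[["alpha"]] <= 0 || location[["alpha"]] > 1)
    stop("f must lie in [0,1] and alpha in (0,1]", call. = FALSE)
  if (afp_positive_rate < 0 || afp_positive_rate > 1)
    stop("'afp_positive_rate' must lie in [0,1]", call. = FALSE)
  sd <- ifelse(spread_type == "iqr", spread / 1.349, spread)
  names(sd) <- pars
  structure(list(location = location, sd = sd, spread = spread,
                 spread_type = stats::setNames(spread_type, pars),
                 afp_positive_rate = afp_positive_rate,
                 voxel_cv = voxel_cv, s0 = s0, label = label),
            class = "class_distribution_spec")
}

#' @export
print.class_distribution_spec <- function(x, ...) {
  cat(sprintf("class spec '%s' (AFP+ rate %.3f)\n", x$label,
              x$afp_positive_rate))
  print(round(rbind(location = x$location, sd = x$sd), 4))
  invisible(x)
}

#' Built-in class specifications for the two Ki-67 expression classes
#'
#' Training-cohort class-wise locations and spreads of the whole-tumor mean
#' of each parameter map, and the class-conditional AFP-positive rates
#' (24/46 for high, 6/34 for low Ki-67 expression). Coefficients in
#' 10^-3 mm^2/s. Spreads presented as median +/- IQR in the source
#' summaries are tagged `"iqr"` and converted internally.
#'
#' @return a `class_distribution_spec`.
#' @export
hcc_high_ki67_spec <- function() {
  class_distribution_spec(
    location = c(adc = 1.30, d = 0.83, d_star = 59.48, f = 0.13,
                 ddc = 0.96, alpha = 0.65),
    spread = c(adc = 0.32, d = 0.21, d_star = 27.74, f = 0.07,
               ddc = 0.32, alpha = 0.13),
    spread_type = c("iqr", "iqr", "sd", "iqr", "iqr", "sd"),
    afp_positive_rate = 24 / 46,
    label = "high Ki-67 (>20%)")
}

#' @rdname hcc_high_ki67_spec
#' @export
hcc_low_ki67_spec <- function() {
  class_distribution_spec(
    location = c(adc = 1.50, d = 0.92, d_star = 55.12, f = 0.20,
                 ddc = 1.15, alpha = 0.62),
    spread = c(adc = 0.67, d = 0.47, d_star = 32.96, f = 0.13,
               ddc = 0.60, alpha = 0.13),
    spread_type = c("iqr", "iqr", "sd", "iqr", "iqr", "sd"),
    afp_positive_rate = 6 / 34,
    label = "low Ki-67 (<=20%)")
}

# one log-normal / logit-normal draw vector for a parameter
.sample_param <- function(par, n, loc, sd) {
  if (sd == 0) return(rep(loc, n))
  if (par %in% c("f", "alpha")) {
    mu <- stats::qlogis(loc)
    sigma <- sd / (loc * (1 - loc))  # delta-method scale on the logit
    stats::plogis(stats::rnorm(n, mu, sigma))
  } else {
    cv <- sd / loc
    sdlog <- sqrt(log(1 + cv^2))
    stats::rlnorm(n, meanlog = log(loc) - sdlog^2 / 2, sdlog = sdlog)
  }
}

#' Sample ground-truth parameter maps over an ROI
#'
#' Draws independent per-voxel ground-truth parameters from the spec's
#' distribution families (log-normal for coefficients, parameterized so the
#' arithmetic mean equals the location; logit-normal for f and alpha).
#' Reproducible given `seed`.
#'
#' @param spec a [class_distribution_spec].
#' @param mask 3D binary array; must be non-empty.
#' @param seed integer seed, or NULL to use the current RNG state.
#' @return a `param_maps` object holding truth maps for all six parameters
#'   plus `s0`.
#' @export
sample_truth_maps <- function(spec, mask, seed = NULL) {
  stopifnot(inherits(spec, "class_distribution_spec"))
  mask <- .validate_mask(mask, min_voxels = 1L)
  if (!is.null(seed)) set.seed(seed)
  idx <- which(mask)
  n <- length(idx)
  sp <- dim(mask)
  maps <- lapply(names(spec$location), function(par) {
    arr <- array(NA_real_, dim = sp)
    arr[idx] <- .sample_param(par, n, spec$location[[par]], spec$sd[[par]])
    arr
  })
  names(maps) <- names(spec$location)
  maps$s0 <- array(NA_real_, dim = sp)
  maps$s0[idx] <- spec$s0
  structure(list(maps = maps, mask = mask, scheme = NULL,
                 diagnostics = NULL, n_voxels = n, n_unfittable = 0L),
            class = "param_maps")
}

#' Render a DWI series from truth maps
#'
#' Evaluates the chosen forward model per voxel over the scheme and applies
#' Rician corruption: the magnitude of (signal + N(0, sigma)) + i N(0, sigma).
#' `sigma = 0` returns the noiseless signal exactly. Background voxels hold
#' pure noise.
#'
#' @param truth a `param_maps` with ground-truth maps (see
#'   [sample_truth_maps()]).
#' @param scheme a [bvalue_scheme].
#' @param model generating model: `"biexp"` (default), `"mono"` or
#'   `"stretched"`.
#' @param sigma Rician noise level in signal units (>= 0).
#' @param seed integer seed, or NULL.
#' @return a [dwi_series()].
#' @export
render_dwi <- function(truth, scheme, model = c("biexp", "mono", "stretched"),
                       sigma = 0, seed = NULL) {
  stopifnot(inherits(truth, "param_maps"))
  model <- match.arg(model)
  b <- unclass(bvalue_scheme(scheme))
  if (sigma < 0) stop("'sigma' must be >= 0", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  sp <- dim(truth$mask)
  idx <- which(truth$mask)
  m <- truth$maps
  s0 <- m$s0[idx]
  decay <- switch(model,
    mono = exp(-outer(m$adc[idx] * .DIFF_UNIT, b)),
    biexp = (1 - m$f[idx]) * exp(-outer(m$d[idx] * .DIFF_UNIT, b)) +
      m$f[idx] * exp(-outer(m$d_star[idx] * .DIFF_UNIT, b)),
    stretched = exp(-outer(m$ddc[idx] * .DIFF_UNIT, b)^m$alpha[idx]))
  sig4d <- array(0, dim = c(sp, length(b)))
  flat <- matrix(sig4d, ncol = length(b))
  flat[idx, ] <- s0 * decay
  if (sigma > 0) {
    flat <- sqrt((flat + stats::rnorm(length(flat), 0, sigma))^2 +
                   stats::rnorm(length(flat), 0, sigma)^2)
  }
  dwi_series(array(flat, dim = c(sp, length(b))), bvalue_scheme(scheme))
}

# ellipsoid ROI of >= min_voxels voxels centred in a grid
.ellipsoid_mask <- function(grid_dim, semi_axes, min_voxels = 50L) {
  cx <- (grid_dim + 1) / 2
  g <- expand.grid(x = seq_len(grid_dim[1]), y = seq_len(grid_dim[2]),
                   z = seq_len(grid_dim[3]))
  inside <- ((g$x - cx[1]) / semi_axes[1])^2 +
    ((g$y - cx[2]) / semi_axes[2])^2 +
    ((g$z - cx[3]) / semi_axes[3])^2 <= 1
  m <- array(inside, dim = grid_dim)
  if (sum(m) < min_voxels)
    stop("ROI smaller than the minimum voxel support; enlarge the grid or axes",
         call. = FALSE)
  m
}

#' Generate a synthetic two-class cohort of DWI studies
#'
#' One tumor per subject. The class-level spec is re-centred per subject
#' (its spread acting as the inter-subject scale), per-voxel truth is drawn
#' around the subject location with the spec's intra-tumor coefficient of
#' variation, the DWI series is rendered from the generating model with
#' Rician noise, and the AFP covariate is drawn at the class-conditional
#' rate. Fully seeded.
#'
#' @param n_high,n_low class sizes (>= 1); defaults 46 and 34.
#' @param spec_high,spec_low [class_distribution_spec]s.
#' @param scheme a [bvalue_scheme].
#' @param sigma Rician noise level in signal units (spec `s0` is 100, so
#'   2 corresponds to 2% of the baseline signal).
#' @param seed integer seed.
#' @param model generating model tag passed to [render_dwi()]; the
#'   biexponential is the default (richest of the three), a pure
#'   stretched-exponential mode exists for SEM recovery testing.
#' @param grid_dim spatial grid of each subject volume.
#' @param axes_range in-plane and through-plane semi-axis ranges (voxels)
#'   from which each tumor's ellipsoid is drawn.
#' @return list of class `"dwi_cohort"`; each element has `series`, `mask`,
#'   `truth` and `record` (subject id, `ki67_high`, `afp_high`).
#' @export
generate_cohort <- function(n_high = 46, n_low = 34,
                            spec_high = hcc_high_ki67_spec(),
                            spec_low = hcc_low_ki67_spec(),
                            scheme = bvalue_scheme(), sigma = 2, seed = 1,
                            model = "biexp",
                            grid_dim = c(16, 16, 6),
                            axes_range = list(xy = c(3, 4.5), z = c(1.5, 2.5))) {
  if (n_high < 1 || n_low < 1)
    stop("both class sizes must be >= 1", call. = FALSE)
  set.seed(seed)
  classes <- c(rep(1L, n_high), rep(0L, n_low))
  subjects <- vector("list", length(classes))
  for (i in seq_along(classes)) {
    spec <- if (classes[i] == 1L) spec_high else spec_low
    ax <- c(stats::runif(2, axes_range$xy[1], axes_range$xy[2]),
            stats::runif(1, axes_range$z[1], axes_range$z[2]))
    mask <- .ellipsoid_mask(grid_dim, ax)
    subj_loc <- vapply(names(spec$location), function(par)
      .sample_param(par, 1L, spec$location[[par]], spec$sd[[par]]),
      numeric(1))
    subj_spec <- class_distribution_spec(
      location = subj_loc, spread = spec$voxel_cv * subj_loc,
      spread_type = "sd", afp_positive_rate = spec$afp_positive_rate,
      voxel_cv = spec$voxel_cv, s0 = spec$s0, label = spec$label)
    truth <- sample_truth_maps(subj_spec, mask, seed = NULL)
    series <- render_dwi(truth, scheme, model = model, sigma = sigma,
                         seed = NULL)
    record <- data.frame(subject = sprintf("S%03d", i),
                         ki67_high = classes[i],
                         afp_high = stats::rbinom(1L, 1L, spec$afp_positive_rate))
    subjects[[i]] <- list(series = series, mask = mask, truth = truth,
                          record = record)
  }
  structure(subjects, class = "dwi_cohort", seed = seed, model = model,
            sigma = sigma)
}

#' @export
print.dwi_cohort <- function(x, ...) {
  k <- vapply(x, function(s) s$record$ki67_high, numeric(1))
  cat(sprintf("dwi_cohort: %d subjects (%d high / %d low Ki-67), model %s, sigma %.3g\n",
              length(x), sum(k == 1), sum(k == 0), attr(x, "model"),
              attr(x, "sigma")))
  invisible(x)
}

#' Clinical records of a cohort
#'
#' @param cohort a `dwi_cohort`.
#' @return data frame with one row per subject.
#' @export
cohort_records <- function(cohort) {
  do.call(rbind, lapply(cohort, `[[`, "record"))
}

#' Stratified train/test split
#'
#' Splits a cohort (or any per-subject data frame with a `ki67_high`
#' column) into disjoint, exhaustive train and test subsets, stratified by
#' Ki-67 class. The total test size is `round((1 - ratio) * n)` and is
#' apportioned to the classes by largest-remainder rounding of their
#' proportional quotas, so each class keeps its share within one subject.
#' Seeded.
#'
#' @param x a `dwi_cohort` or a data frame with a `ki67_high` column.
#' @param ratio training proportion in (0, 1).
#' @param seed integer seed.
#' @return list with elements `train` and `test` of the same type as `x`.
#' @export
split_train_test <- function(x, ratio = 0.8, seed = 1) {
  if (ratio <= 0 || ratio >= 1)
    stop("'ratio' must lie strictly inside (0, 1)", call. = FALSE)
  cls <- if (is.data.frame(x)) x$ki67_high else
    vapply(x, function(s) s$record$ki67_high, numeric(1))
  if (is.null(cls)) stop("no 'ki67_high' stratification variable", call. = FALSE)
  set.seed(seed)
  strata <- sort(unique(cls), decreasing = TRUE)
  sizes <- vapply(strata, function(k) sum(cls == k), integer(1))
  n_test_total <- max(length(strata), round((1 - ratio) * length(cls)))
  quota <- (1 - ratio) * sizes
  n_test <- pmax(1L, floor(quota))
  seats <- n_test_total - sum(n_test)
  if (seats > 0) {
    pref <- order(quota - floor(quota), sizes, decreasing = TRUE)
    for (j in pref[seq_len(min(seats, length(pref)))])
      n_test[j] <- n_test[j] + 1L
  }
  if (any(n_test >= sizes))
    stop("a training stratum would be empty", call. = FALSE)
  test_idx <- integer(0)
  for (j in seq_along(strata))
    test_idx <- c(test_idx, sample(which(cls == strata[j]), n_test[j]))
  test_idx <- sort(test_idx)
  if (is.data.frame(x)) {
    list(train = x[-test_idx, , drop = FALSE],
         test = x[test_idx, , drop = FALSE])
  } else {
    tr <- x[-test_idx]; te <- x[test_idx]
    attributes(tr) <- attributes(x)[setdiff(names(attributes(x)), "names")]
    attributes(te) <- attributes(x)[setdiff(names(attributes(x)), "names")]
    list(train = tr, test = te)
  }
}

#' Read / write a class distribution specification as YAML
#'
#' @param path YAML file path.
#' @return for reading, a validated [class_distribution_spec()].
#' @export
read_class_spec <- function(path) {
  y <- yaml::read_yaml(path)
  class_distribution_spec(
    location = unlist(y$location), spread = unlist(y$spread),
    spread_type = unlist(y$spread_type),
    afp_positive_rate = y$afp_positive_rate,
    voxel_cv = y$voxel_cv %||% 0.2, s0 = y$s0 %||% 100,
    label = y$label %||% "")
}

#' @rdname read_class_spec
#' @param spec a [class_distribution_spec()].
#' @export
write_class_spec <- function(spec, path) {
  stopifnot(inherits(spec, "class_distribution_spec"))
  yaml::write_yaml(list(
    label = spec$label, location = as.list(spec$location),
    spread = as.list(spec$spread),
    spread_type = as.list(spec$spread_type),
    afp_positive_rate = spec$afp_positive_rate,
    voxel_cv = spec$voxel_cv, s0 = spec$s0), path, precision = 15)
  invisible(path)
}
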