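# Voxelwise estimation of ADC, (D, D*, f) and (DDC, alpha) from
# multi-b-value signal decays.

#' Fitting configuration
#'
#' Bounds, the IVIM split point and optimizer controls shared by the
#' nonlinear fitters. Bounds on diffusion coefficients are in
#' 10^-3 mm^2/s. The D* bounds default to \[3, 200\], the range outside of
#' which voxel estimates are clamped; the perfusion fraction is always
#' constrained to \[0, 1\] and alpha to (0, 1\].
#'
#' @param ivim_split_b b-value (s/mm^2) separating the perfusion-dominated
#'   and diffusion-dominated regimes of the segmented IVIM fit. Must lie
#'   strictly inside the scheme's range.
#' @param d_bounds,dstar_bounds,ddc_bounds lower/upper bounds for D, D* and
#'   DDC (10^-3 mm^2/s).
#' @param alpha_bounds bounds for the heterogeneity index; upper bound is
#'   fixed at 1.
#' @param refine if `TRUE` (default) the segmented IVIM estimates are
#'   polished by a bounded Levenberg-Marquardt pass over all four
#'   parameters; the segmented step remains the initializer.
#' @param ftol,ptol,maxit Levenberg-Marquardt convergence controls.
#' @return list of class `"fit_config"`.
#' @export
fit_config <- function(ivim_split_b = 200,
                       d_bounds = c(0.01, 5),
                       dstar_bounds = c(3, 200),
                       ddc_bounds = c(0.01, 20),
                       alpha_bounds = c(0.05, 1),
                       refine = TRUE,
                       ftol = 1e-10, ptol = 1e-10, maxit = 200L) {
  for (b in list(d_bounds, dstar_bounds, ddc_bounds, alpha_bounds)) {
    if (length(b) != 2L || !all(is.finite(b)) || b[1] >= b[2])
      stop("each bound pair must be finite with lower < upper", call. = FALSE)
  }
  if (alpha_bounds[2] != 1)
    stop("the upper alpha bound is 1 by definition", call. = FALSE)
  if (ivim_split_b <= 0)
    stop("'ivim_split_b' must be positive", call. = FALSE)
  structure(list(ivim_split_b = ivim_split_b, d_bounds = d_bounds,
                 dstar_bounds = dstar_bounds, ddc_bounds = ddc_bounds,
                 alpha_bounds = alpha_bounds, refine = isTRUE(refine),
                 ftol = ftol, ptol = ptol, maxit = as.integer(maxit)),
            class = "fit_config")
}

# ---- single-curve fit container -------------------------------------------

new_dwi_fit <- function(model, estimates, b, signal, fitted, converged,
                        flagged, note = NA_character_) {
  res <- if (is.null(fitted)) rep(NA_real_, length(signal)) else signal - fitted
  structure(list(model = model, estimates = estimates, b = b, signal = signal,
                 fitted = fitted, residuals = res,
                 residual_norm = sqrt(sum(res^2)),
                 converged = converged, flagged = flagged, note = note),
            class = "dwi_fit")
}

.unfittable <- function(model, b, signal, note) {
  est <- switch(model,
                mono = c(s0 = NA_real_, adc = NA_real_),
                biexp = c(s0 = NA_real_, d = NA_real_, d_star = NA_real_,
                          f = NA_real_),
                stretched = c(s0 = NA_real_, ddc = NA_real_, alpha = NA_real_))
  new_dwi_fit(model, est, b, signal, NULL, converged = FALSE, flagged = TRUE,
              note = note)
}

#' @export
print.dwi_fit <- function(x, ...) {
  cat(sprintf("%s-model DWI fit (%d b-values)\n", x$model, length(x$b)))
  print(round(x$estimates, 5))
  cat(sprintf("residual norm %.4g | converged: %s%s\n", x$residual_norm,
              x$converged, if (x$flagged) " | FLAGGED" else ""))
  if (!is.na(x$note)) cat("note:", x$note, "\n")
  invisible(x)
}

#' @export
coef.dwi_fit <- function(object, ...) object$estimates

#' @export
residuals.dwi_fit <- function(object, ...) object$residuals

#' Predict signal from a fitted decay model
#'
#' @param object a `dwi_fit`.
#' @param b b-values at which to evaluate the fitted curve; defaults to the
#'   ones used for fitting.
#' @param ... unused.
#' @return numeric signal vector.
#' @export
predict.dwi_fit <- function(object, b = object$b, ...) {
  e <- object$estimates
  if (anyNA(e)) stop("cannot predict from an unfittable voxel", call. = FALSE)
  b <- .as_b(b)
  switch(object$model,
         mono = .mono_curve(b, e[["s0"]], e[["adc"]]),
         biexp = .biexp_curve(b, e[["s0"]], e[["d"]], e[["d_star"]], e[["f"]]),
         stretched = .stretched_curve(b, e[["s0"]], e[["ddc"]], e[["alpha"]]))
}

#' @export
plot.dwi_fit <- function(x, ...) {
  graphics::plot(x$b, x$signal, xlab = "b (s/mm^2)", ylab = "signal",
                 main = sprintf("%s fit", x$model), ...)
  if (!anyNA(x$estimates)) {
    bb <- seq(min(x$b), max(x$b), length.out = 200)
    graphics::lines(bb, predict(x, bb))
  }
  invisible(x)
}

# snap an estimate sitting (numerically) on a box bound to the exact bound
.snap_bound <- function(x, bounds) {
  tol <- 1e-6 * pmax(1, abs(bounds))
  if (x <= bounds[1] + tol[1]) return(bounds[1])
  if (x >= bounds[2] - tol[2]) return(bounds[2])
  x
}

.clamp <- function(x, bounds) min(max(x, bounds[1]), bounds[2])

# ---- monoexponential -------------------------------------------------------

#' Fit the monoexponential (ADC) model
#'
#' Unweighted log-linear least squares of `log S` on b over all b-values.
#' Exact on noiseless monoexponential input. Voxels with non-positive
#' signal, or whose fitted ADC is non-positive (e.g. constant signal), are
#' flagged and excluded from downstream histogram support.
#'
#' @param signal per-voxel signal vector, one value per b.
#' @param b a [bvalue_scheme] or numeric b vector (>= 2 values).
#' @return a `dwi_fit` with estimates `s0` and `adc` (10^-3 mm^2/s).
#' @examples
#' fit_mono(c(1, exp(-1.5)), c(0, 1000))  # adc = 1.5
#' @export
fit_mono <- function(signal, b) {
  b <- .as_b(b)
  if (length(signal) != length(b) || length(b) < 2L)
    stop("'signal' and 'b' must match, with at least 2 b-values", call. = FALSE)
  if (any(!is.finite(signal)) || any(signal <= 0))
    return(.unfittable("mono", b, signal, "non-positive or non-finite signal"))
  co <- stats::lm.fit(cbind(1, b), log(signal))$coefficients
  s0 <- exp(co[[1]])
  adc <- -co[[2]] / .DIFF_UNIT
  flag <- !is.finite(adc) || adc <= 0
  fitted <- if (flag) NULL else .mono_curve(b, s0, adc)
  new_dwi_fit("mono", c(s0 = s0, adc = adc), b, signal, fitted,
              converged = TRUE, flagged = flag,
              note = if (flag) "non-positive adc" else NA_character_)
}

# ---- biexponential (segmented IVIM) ---------------------------------------

#' Fit the biexponential (IVIM) model
#'
#' Segmented fit: (1) log-linear regression over b >= `ivim_split_b` gives D
#' and the extrapolated intercept, whence f = 1 - S_int/S(0); (2) a bounded
#' one-dimensional search fits D* on the full curve with D, f and s0 held;
#' (3) optionally (default) a bounded Levenberg-Marquardt pass refines all
#' four parameters from that starting point. D* is clamped to the
#' configured \[3, 200\] x 10^-3 mm^2/s box and f to \[0, 1\]; estimates on
#' a bound are returned exactly at the bound.
#'
#' @inheritParams fit_mono
#' @param cfg a [fit_config].
#' @return a `dwi_fit` with estimates `s0`, `d`, `d_star`, `f`.
#' @examples
#' b <- bvalue_scheme()
#' fit_biexp(biexp_signal(b, d = 0.83, d_star = 59.48, f = 0.13), b)
#' @export
fit_biexp <- function(signal, b, cfg = fit_config()) {
  b <- .as_b(b)
  if (length(signal) != length(b))
    stop("'signal' and 'b' must have equal length", call. = FALSE)
  split <- cfg$ivim_split_b
  if (split <= min(b) || split > max(b))
    stop("'ivim_split_b' must lie strictly inside the b range", call. = FALSE)
  if (sum(b > split) < 3L || sum(b <= split) < 2L)
    stop("need >= 3 b-values above and >= 2 at/below the IVIM split",
         call. = FALSE)
  if (any(!is.finite(signal)) || any(signal <= 0))
    return(.unfittable("biexp", b, signal, "non-positive or non-finite signal"))

  s0 <- signal[which.min(b)]
  hi <- b >= split
  co <- stats::lm.fit(cbind(1, b[hi]), log(signal[hi]))$coefficients
  d <- .clamp(-co[[2]] / .DIFF_UNIT, cfg$d_bounds)
  f <- .clamp(1 - exp(co[[1]]) / s0, c(0, 1))

  ssq <- function(ds) sum((signal - .biexp_curve(b, s0, d, ds, f))^2)
  if (f > 1e-12) {
    opt <- stats::optimize(ssq, interval = cfg$dstar_bounds, tol = 1e-8)
    cand <- c(opt$minimum, cfg$dstar_bounds)
    d_star <- cand[which.min(vapply(cand, ssq, numeric(1)))]
  } else {
    d_star <- cfg$dstar_bounds[1]  # unidentifiable when f = 0
  }
  converged <- TRUE

  if (cfg$refine && f > 1e-12) {
    resfn <- function(p) signal - .biexp_curve(b, p[1], p[2], p[4], p[3])
    lm <- minpack.lm::nls.lm(
      par = c(s0, d, f, d_star),
      lower = c(1e-12, cfg$d_bounds[1], 0, cfg$dstar_bounds[1]),
      upper = c(10 * max(signal), cfg$d_bounds[2], 1, cfg$dstar_bounds[2]),
      fn = resfn,
      control = minpack.lm::nls.lm.control(ftol = cfg$ftol, ptol = cfg$ptol,
                                           maxiter = cfg$maxit))
    converged <- lm$info %in% 1:3
    s0 <- lm$par[1]; d <- lm$par[2]; f <- lm$par[3]; d_star <- lm$par[4]
  }

  d_star <- .snap_bound(d_star, cfg$dstar_bounds)
  f <- .clamp(f, c(0, 1))
  est <- c(s0 = s0, d = d, d_star = d_star, f = f)
  new_dwi_fit("biexp", est, b, signal, .biexp_curve(b, s0, d, d_star, f),
              converged = converged, flagged = !converged,
              note = if (!converged) "optimizer did not converge" else NA_character_)
}

# ---- stretched exponential -------------------------------------------------

#' Fit the stretched-exponential model
#'
#' Bounded Levenberg-Marquardt least squares over (s0, DDC, alpha) with
#' alpha constrained to (0, 1], initialized from the monoexponential fit
#' (alpha0 = 0.9, DDC0 = fitted ADC). Exact on noiseless
#' stretched-exponential input; an estimate on the alpha = 1 boundary is
#' returned exactly at 1. A DDC estimate stuck at its lower bound marks the
#' voxel as degenerate.
#'
#' @inheritParams fit_biexp
#' @return a `dwi_fit` with estimates `s0`, `ddc` (10^-3 mm^2/s), `alpha`.
#' @examples
#' b <- bvalue_scheme()
#' fit_stretched(stretched_signal(b, ddc = 0.96, alpha = 0.65), b)
#' @export
fit_stretched <- function(signal, b, cfg = fit_config()) {
  b <- .as_b(b)
  if (length(signal) != length(b) || length(b) < 3L)
    stop("need at least 3 b-values", call. = FALSE)
  if (any(!is.finite(signal)) || any(signal <= 0))
    return(.unfittable("stretched", b, signal,
                       "non-positive or non-finite signal"))
  mono <- fit_mono(signal, b)
  s0_0 <- if (is.finite(mono$estimates[["s0"]])) mono$estimates[["s0"]] else signal[1]
  ddc_0 <- .clamp(mono$estimates[["adc"]], cfg$ddc_bounds)
  if (!is.finite(ddc_0)) ddc_0 <- cfg$ddc_bounds[1]

  resfn <- function(p) signal - .stretched_curve(b, p[1], p[2], p[3])
  lm <- minpack.lm::nls.lm(
    par = c(s0_0, ddc_0, 0.9),
    lower = c(1e-12, cfg$ddc_bounds[1], cfg$alpha_bounds[1]),
    upper = c(10 * max(signal), cfg$ddc_bounds[2], 1),
    fn = resfn,
    control = minpack.lm::nls.lm.control(ftol = cfg$ftol, ptol = cfg$ptol,
                                         maxiter = cfg$maxit))
  converged <- lm$info %in% 1:3
  s0 <- lm$par[1]
  ddc <- .snap_bound(lm$par[2], cfg$ddc_bounds)
  alpha <- .snap_bound(lm$par[3], cfg$alpha_bounds)
  degenerate <- ddc <= cfg$ddc_bounds[1]
  est <- c(s0 = s0, ddc = ddc, alpha = alpha)
  new_dwi_fit("stretched", est, b, signal, .stretched_curve(b, s0, ddc, alpha),
              converged = converged, flagged = !converged || degenerate,
              note = if (degenerate) "ddc at lower bound" else
                if (!converged) "optimizer did not converge" else NA_character_)
}

# ---- whole-ROI fitting -----------------------------------------------------

#' Fit all three models over an ROI
#'
#' Applies the monoexponential, biexponential and stretched-exponential
#' fitters to every voxel of the ROI and assembles per-voxel parameter maps
#' (NA outside the ROI and at unfittable voxels) together with fit
#' diagnostics. Deterministic given inputs and configuration.
#'
#' @param series a `dwi_series` (see [dwi_series()]).
#' @param mask 3D logical array matching the spatial grid of `series`.
#' @param cfg a [fit_config].
#' @param models subset of `c("mono", "biexp", "stretched")` to fit.
#' @return object of class `"param_maps"`: a list with `maps` (named 3D
#'   arrays `adc`, `d`, `d_star`, `f`, `ddc`, `alpha`), the `mask`,
#'   `scheme`, a per-voxel `diagnostics` data frame and unfittable counts.
#' @export
fit_roi <- function(series, mask, cfg = fit_config(),
                    models = c("mono", "biexp", "stretched")) {
  stopifnot(inherits(series, "dwi_series"))
  models <- match.arg(models, several.ok = TRUE)
  sp <- dim(series$signal)[1:3]
  mask <- .validate_mask(mask, sp, min_voxels = 1L)
  b <- series$scheme
  idx <- which(mask)
  nb <- length(b)
  sig <- matrix(series$signal, ncol = nb)[idx, , drop = FALSE]

  empty_map <- function() array(NA_real_, dim = sp)
  maps <- list(adc = empty_map(), d = empty_map(), d_star = empty_map(),
               f = empty_map(), ddc = empty_map(), alpha = empty_map())
  nv <- length(idx)
  diag <- data.frame(voxel = idx,
                     fittable = rep(TRUE, nv),
                     mono_flagged = NA, biexp_converged = NA,
                     sem_converged = NA, sem_flagged = NA,
                     biexp_resid = NA_real_, sem_resid = NA_real_)

  for (v in seq_len(nv)) {
    s <- sig[v, ]
    if (any(!is.finite(s)) || any(s <= 0)) {
      diag$fittable[v] <- FALSE
      next
    }
    if ("mono" %in% models) {
      fm <- fit_mono(s, b)
      diag$mono_flagged[v] <- fm$flagged
      if (!fm$flagged) maps$adc[idx[v]] <- fm$estimates[["adc"]]
    }
    if ("biexp" %in% models) {
      fb <- fit_biexp(s, b, cfg)
      diag$biexp_converged[v] <- fb$converged
      diag$biexp_resid[v] <- fb$residual_norm
      maps$d[idx[v]] <- fb$estimates[["d"]]
      maps$d_star[idx[v]] <- fb$estimates[["d_star"]]
      maps$f[idx[v]] <- fb$estimates[["f"]]
    }
    if ("stretched" %in% models) {
      fs <- fit_stretched(s, b, cfg)
      diag$sem_converged[v] <- fs$converged
      diag$sem_flagged[v] <- fs$flagged
      diag$sem_resid[v] <- fs$residual_norm
      if (!fs$flagged) {
        maps$ddc[idx[v]] <- fs$estimates[["ddc"]]
        maps$alpha[idx[v]] <- fs$estimates[["alpha"]]
      }
    }
  }

  n_unfit <- sum(!diag$fittable)
  if (n_unfit == nv)
    stop("all ROI voxels are unfittable", call. = FALSE)
  if (n_unfit > 0.2 * nv)
    warning(sprintf("%d of %d ROI voxels (%.0f%%) unfittable", n_unfit, nv,
                    100 * n_unfit / nv), call. = FALSE)

  structure(list(maps = maps[.map_names(models)], mask = mask, scheme = b,
                 diagnostics = diag, n_voxels = nv, n_unfittable = n_unfit),
            class = "param_maps")
}

.map_names <- function(models) {
  out <- character(0)
  if ("mono" %in% models) out <- c(out, "adc")
  if ("biexp" %in% models) out <- c(out, "d", "d_star", "f")
  if ("stretched" %in% models) out <- c(out, "ddc", "alpha")
  out
}

#' @export
print.param_maps <- function(x, ...) {
  cat(sprintf("param_maps: %s over %d ROI voxels (%d unfittable)\n",
              paste(names(x$maps), collapse = ", "), x$n_voxels,
              x$n_unfittable))
  invisible(x)
}

#' Extract the ROI values of one parameter map
#'
#' @param pm a `param_maps` object.
#' @param map map name, e.g. `"ddc"`.
#' @param drop_na drop NA (unfittable) voxels (default TRUE).
#' @return numeric vector of per-voxel values.
#' @export
map_values <- function(pm, map, drop_na = TRUE) {
  stopifnot(inherits(pm, "param_maps"))
  if (!map %in% names(pm$maps))
    stop(sprintf("no map '%s' (have: %s)", map,
                 paste(names(pm$maps), collapse = ", ")), call. = FALSE)
  v <- pm$maps[[map]][pm$mask]
  if (drop_na) v <- v[!is.na(v)]
  v
}

.validate_mask <- function(mask, sp = NULL, min_voxels = 1L) {
  if (!is.array(mask) || length(dim(mask)) != 3L)
    stop("mask must be a 3D array", call. = FALSE)
  if (!is.null(sp) && !all(dim(mask) == sp))
    stop("mask grid does not match the image grid", call. = FALSE)
  m <- array(as.logical(mask), dim(mask))
  if (anyNA(m)) stop("mask must be binary without NA", call. = FALSE)
  if (sum(m) < min_voxels)
    stop(sprintf("mask has fewer than %d foreground voxels", min_voxels),
         call. = FALSE)
  m
}
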