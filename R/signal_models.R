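# Forward signal equations for the three diffusion decay models.
# All diffusion coefficients (adc, d, d_star, ddc) are expressed in the
# display unit 10^-3 mm^2/s throughout the package; the decay exponent is
# b * coefficient * 1e-3 with b in s/mm^2.

.DIFF_UNIT <- 1e-3

#' Diffusion b-value scheme
#'
#' Constructs and validates the ordered set of diffusion weightings of a
#' multi-b-value DWI acquisition. The default is the nine-point scheme used
#' throughout the package (0, 10, 20, 40, 80, 200, 400, 600, 1000 s/mm^2).
#'
#' @param values numeric vector of b-values in s/mm^2. Must be strictly
#'   increasing, start at 0 and contain at least 4 values (the nonlinear
#'   fitters need degrees of freedom).
#' @return a numeric vector of class `"bvalue_scheme"`.
#' @examples
#' bvalue_scheme()
#' bvalue_scheme(c(0, 50, 400, 800))
#' @export
bvalue_scheme <- function(values = c(0, 10, 20, 40, 80, 200, 400, 600, 1000)) {
  values <- as.numeric(values)
  if (length(values) < 4L)
    stop("a b-value scheme needs at least 4 values", call. = FALSE)
  if (anyNA(values) || any(values < 0))
    stop("b-values must be finite and non-negative", call. = FALSE)
  if (values[1L] != 0)
    stop("the first b-value must be 0 (baseline signal)", call. = FALSE)
  if (any(diff(values) <= 0))
    stop("b-values must be strictly increasing", call. = FALSE)
  structure(values, class = "bvalue_scheme")
}

#' @export
print.bvalue_scheme <- function(x, ...) {
  cat("b-value scheme (s/mm^2):", paste(unclass(x), collapse = ", "), "\n")
  invisible(x)
}

# Coerce a scheme or plain numeric b vector for signal evaluation.
.as_b <- function(b) {
  b <- as.numeric(b)
  if (anyNA(b) || any(b < 0))
    stop("b-values must be finite and non-negative", call. = FALSE)
  b
}

.check_positive <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0)
    stop(sprintf("'%s' must be a single positive number", name), call. = FALSE)
}

# Unvalidated curve evaluators, shared with the optimizers where trial
# parameters may transiently violate the physical invariants.
.mono_curve <- function(b, s0, adc) s0 * exp(-b * adc * .DIFF_UNIT)

.biexp_curve <- function(b, s0, d, d_star, f) {
  s0 * ((1 - f) * exp(-b * d * .DIFF_UNIT) + f * exp(-b * d_star * .DIFF_UNIT))
}

.stretched_curve <- function(b, s0, ddc, alpha) {
  s0 * exp(-(b * ddc * .DIFF_UNIT)^alpha)
}

#' Monoexponential DWI signal
#'
#' Evaluates `S(b) = s0 * exp(-b * ADC)` over a b-value scheme.
#'
#' @param b a [bvalue_scheme] or numeric vector of b-values (s/mm^2).
#' @param adc apparent diffusion coefficient, 10^-3 mm^2/s (> 0).
#' @param s0 baseline signal at b = 0 (> 0).
#' @return numeric signal vector, one value per b.
#' @examples
#' mono_signal(bvalue_scheme(), adc = 1.30)
#' @export
mono_signal <- function(b, adc, s0 = 1) {
  .check_positive(s0, "s0")
  .check_positive(adc, "adc")
  .mono_curve(.as_b(b), s0, adc)
}

#' Biexponential (IVIM) DWI signal
#'
#' Evaluates the intravoxel-incoherent-motion decay
#' `S(b) = s0 * ((1 - f) exp(-b D) + f exp(-b D*))`, where D is the true
#' (tissue) diffusion coefficient, D* the perfusion-linked pseudo-diffusion
#' coefficient and f the perfusion fraction.
#'
#' @inheritParams mono_signal
#' @param d true diffusion coefficient, 10^-3 mm^2/s (> 0).
#' @param d_star pseudo-diffusion coefficient, 10^-3 mm^2/s (>= d).
#' @param f perfusion fraction in \[0, 1\].
#' @return numeric signal vector.
#' @examples
#' biexp_signal(bvalue_scheme(), d = 0.83, d_star = 59.48, f = 0.13)
#' @export
biexp_signal <- function(b, d, d_star, f, s0 = 1) {
  .check_positive(s0, "s0")
  .check_positive(d, "d")
  .check_positive(d_star, "d_star")
  if (d_star < d)
    stop("'d_star' must be >= 'd' (pseudo-diffusion is the fast compartment)",
         call. = FALSE)
  if (!is.numeric(f) || length(f) != 1L || !is.finite(f) || f < 0 || f > 1)
    stop("'f' must lie in [0, 1]", call. = FALSE)
  .biexp_curve(.as_b(b), s0, d, d_star, f)
}

#' Stretched-exponential DWI signal
#'
#' Evaluates `S(b) = s0 * exp(-(b * DDC)^alpha)`, the standard
#' stretched-exponential form with distributed diffusion coefficient DDC and
#' heterogeneity index alpha in (0, 1]; alpha = 1 reduces to the
#' monoexponential model.
#'
#' @inheritParams mono_signal
#' @param ddc distributed diffusion coefficient, 10^-3 mm^2/s (> 0).
#' @param alpha heterogeneity index in (0, 1].
#' @return numeric signal vector.
#' @examples
#' stretched_signal(bvalue_scheme(), ddc = 0.96, alpha = 0.65)
#' @export
stretched_signal <- function(b, ddc, alpha, s0 = 1) {
  .check_positive(s0, "s0")
  .check_positive(ddc, "ddc")
  if (!is.numeric(alpha) || length(alpha) != 1L || !is.finite(alpha) ||
      alpha <= 0 || alpha > 1)
    stop("'alpha' must lie in (0, 1]", call. = FALSE)
  .stretched_curve(.as_b(b), s0, ddc, alpha)
}
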