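# Independent oracles used by the tests: multi-resolution grid searches
# for the nonlinear fitters (refined until the grid spacing is below 0.1%
# of each parameter), and random truth generators drawn from the built-in
# class specifications.

b9 <- bvalue_scheme()

# Sum of squares of a biexponential candidate over a b vector, vectorized
# over a parameter grid (rows).
.ssq_biexp_grid <- function(signal, b, s0, grid) {
  pred <- s0 * ((1 - grid$f) * exp(-outer(grid$d * 1e-3, b)) +
                  grid$f * exp(-outer(grid$d_star * 1e-3, b)))
  rowSums((pred - matrix(signal, nrow(grid), length(b), byrow = TRUE))^2)
}

grid_search_biexp <- function(signal, b, s0 = signal[1],
                              d_range = c(0.1, 3), f_range = c(0, 0.6),
                              ds_range = c(3, 200), n = 9, iters = 9) {
  lo <- c(d_range[1], f_range[1], ds_range[1])
  hi <- c(d_range[2], f_range[2], ds_range[2])
  lo0 <- lo; hi0 <- hi
  best <- NULL
  for (it in seq_len(iters)) {
    ax <- lapply(1:3, function(j) seq(lo[j], hi[j], length.out = n))
    grid <- expand.grid(d = ax[[1]], f = ax[[2]], d_star = ax[[3]])
    ssq <- .ssq_biexp_grid(signal, b, s0, grid)
    k <- which.min(ssq)
    best <- list(par = unlist(grid[k, ]), ssq = ssq[k])
    step <- (hi - lo) / (n - 1)
    lo <- pmax(lo0, best$par - step)
    hi <- pmin(hi0, best$par + step)
  }
  best$residual_norm <- sqrt(best$ssq)
  best
}

.ssq_sem_grid <- function(signal, b, s0, grid) {
  pred <- s0 * exp(-outer(grid$ddc * 1e-3, b)^grid$alpha)
  rowSums((pred - matrix(signal, nrow(grid), length(b), byrow = TRUE))^2)
}

grid_search_stretched <- function(signal, b, s0 = signal[1],
                                  ddc_range = c(0.1, 4),
                                  alpha_range = c(0.2, 1), n = 15,
                                  iters = 9) {
  lo <- c(ddc_range[1], alpha_range[1])
  hi <- c(ddc_range[2], alpha_range[2])
  lo0 <- lo; hi0 <- hi
  best <- NULL
  for (it in seq_len(iters)) {
    ax <- lapply(1:2, function(j) seq(lo[j], hi[j], length.out = n))
    grid <- expand.grid(ddc = ax[[1]], alpha = ax[[2]])
    ssq <- .ssq_sem_grid(signal, b, s0, grid)
    k <- which.min(ssq)
    best <- list(par = unlist(grid[k, ]), ssq = ssq[k])
    step <- (hi - lo) / (n - 1)
    lo <- pmax(lo0, best$par - step)
    hi <- pmin(hi0, best$par + step)
  }
  best$residual_norm <- sqrt(best$ssq)
  best
}

# Random valid truth draws from the built-in class distributions,
# restricted to the fitter's identifiable box.
random_biexp_truth <- function(n, seed) {
  set.seed(seed)
  spec <- list(hcc_high_ki67_spec(), hcc_low_ki67_spec())
  out <- data.frame(d = numeric(0), d_star = numeric(0), f = numeric(0))
  while (nrow(out) < n) {
    s <- spec[[sample(2, 1)]]
    d <- dwihist:::.sample_param("d", 1, s$location[["d"]], s$sd[["d"]])
    ds <- dwihist:::.sample_param("d_star", 1, s$location[["d_star"]],
                                  s$sd[["d_star"]])
    f <- dwihist:::.sample_param("f", 1, s$location[["f"]], s$sd[["f"]])
    if (ds >= 10 && ds <= 200 && d > 0.1 && d < 3 && f >= 0.02 && f <= 0.6)
      out[nrow(out) + 1L, ] <- c(d, ds, f)
  }
  out
}

random_sem_truth <- function(n, seed) {
  set.seed(seed)
  spec <- list(hcc_high_ki67_spec(), hcc_low_ki67_spec())
  out <- data.frame(ddc = numeric(0), alpha = numeric(0))
  while (nrow(out) < n) {
    s <- spec[[sample(2, 1)]]
    ddc <- dwihist:::.sample_param("ddc", 1, s$location[["ddc"]],
                                   s$sd[["ddc"]])
    al <- dwihist:::.sample_param("alpha", 1, s$location[["alpha"]],
                                  s$sd[["alpha"]])
    if (ddc > 0.1 && ddc < 4 && al >= 0.25 && al <= 0.98)
      out[nrow(out) + 1L, ] <- c(ddc, al)
  }
  out
}

# small ellipsoid mask helper for tests
test_mask <- function(grid = c(12, 12, 5), axes = c(3.5, 3.5, 2)) {
  dwihist:::.ellipsoid_mask(grid, axes)
}
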