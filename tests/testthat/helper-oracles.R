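# Independent oracles used across test files. Each reimplements the target
# quantity by a different route than the package code.

# shortest arc by explicit two-direction minimum
arc_dist_oracle <- function(a, b) {
  d <- abs((a %% (2 * pi)) - (b %% (2 * pi)))
  pmin(d, 2 * pi - d)
}

# circular median objective minimized over a dense grid
grid_median_oracle <- function(theta, grid_n = 1e5) {
  grid <- seq(0, 2 * pi, length.out = grid_n + 1)[-(grid_n + 1)]
  obj <- vapply(grid, function(g) mean(arc_dist_oracle(theta, g)), numeric(1))
  list(angle = grid[which.min(obj)], objective = min(obj))
}

# per-evaluation-point weighted least squares on sin/cos via solve()
wls_ll_oracle <- function(x, y, h, x_eval) {
  vapply(x_eval, function(x0) {
    w <- exp(-(x0 - x)^2 / (2 * h^2))
    X <- cbind(1, x - x0)
    bs <- solve(t(X) %*% (w * X), t(X) %*% (w * sin(y)))[1]
    bc <- solve(t(X) %*% (w * X), t(X) %*% (w * cos(y)))[1]
    atan2(bs, bc) %% (2 * pi)
  }, numeric(1))
}

# Watson U^2 as the anchor-minimized Cramer-von-Mises integral,
# n * integral (Fn(u) - u - c)^2 du with c = mean(Fn - u), on the PIT scale
watson_u2_integral_oracle <- function(u) {
  n <- length(u)
  u <- sort(u)
  grid <- seq(0, 1, length.out = 2e5)
  Fn <- findInterval(grid, u) / n
  dev <- Fn - grid
  c0 <- mean(dev)
  n * mean((dev - c0)^2)
}

# cumulative trapezoid quadrature of a density from an anchor
cdf_quadrature_oracle <- function(dens, from, theta, n_grid = 2e5) {
  vapply(theta, function(th) {
    arc <- (th - from) %% (2 * pi)
    g <- seq(0, arc, length.out = n_grid)
    v <- dens(from + g)
    sum((v[-1] + v[-n_grid]) / 2 * diff(g))
  }, numeric(1))
}
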