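# Independent oracles used across the suite. These re-derive expected
# values from first principles (closed forms, brute-force scans, direct
# summation) and deliberately share no code with the implementation paths
# they check.

# Closed-form solution of the linear two-type ODE system.
oracle_closed_form <- function(b, mu, E0, F0, t) {
  a <- (1 - b) * (1 - mu)
  E <- E0 * exp(a * t)
  # exp(a t) - exp(t) = exp(t) * expm1((a - 1) t), stable when a is near 1
  F <- if (mu == 0) F0 * exp(t) else
    F0 * exp(t) + mu * (1 - b) * E0 * exp(t) * expm1((a - 1) * t) / (a - 1)
  list(E = E, F = F)
}

# Doublings at which the closed-form failed fraction reaches `threshold`,
# by root-finding in time.
oracle_half_failure <- function(b, mu, E0 = 1, F0 = 0, threshold = 0.5,
                                t_max = 200) {
  g <- function(t) {
    s <- oracle_closed_form(b, mu, E0, F0, t)
    s$F / (s$E + s$F) - threshold
  }
  if (g(t_max) < 0) return(NA_real_)
  t50 <- stats::uniroot(g, c(1e-9, t_max), tol = 1e-12)$root
  s <- oracle_closed_form(b, mu, E0, F0, t50)
  log2((s$E + s$F) / (E0 + F0))
}

# Brute-force sliding-window exponential fit: nonlinear LS on every window
# via optim from many starts, on a problem-agnostic parameterisation.
oracle_window_rmax <- function(times, od, window_pts = 9, od_min = 0.03) {
  n <- length(times)
  best <- -Inf
  for (i in seq_len(n - window_pts + 1)) {
    if (od[i] <= od_min) next
    idx <- i:(i + window_pts - 1)
    tt <- times[idx] - times[i]
    yy <- od[idx]
    sse <- function(p) sum((yy - exp(p[1]) * exp(p[2] * tt))^2)
    fits <- lapply(c(0.005, 0.01, 0.02, 0.05), function(r0) {
      stats::optim(c(log(max(yy[1], 1e-6)), r0), sse,
                   control = list(maxit = 2000, reltol = 1e-14))
    })
    r <- fits[[which.min(vapply(fits, `[[`, numeric(1), "value"))]]$par[2]
    if (r > 0 && r > best) best <- r
  }
  if (is.finite(best)) best else NA_real_
}

# Brute-force per-window production-rate fit with (C0, r) taken from an
# OD-window exponential fit; linear LS done via explicit normal equations.
oracle_window_pmax <- function(times, od, fluor, window_pts = 9,
                               od_min = 0.03) {
  n <- length(times)
  best <- -Inf
  for (i in seq_len(n - window_pts + 1)) {
    if (od[i] <= od_min) next
    idx <- i:(i + window_pts - 1)
    tt <- times[idx] - times[i]
    yy <- od[idx]
    sse <- function(p) sum((yy - exp(p[1]) * exp(p[2] * tt))^2)
    fits <- lapply(c(0.005, 0.01, 0.02, 0.05), function(r0) {
      stats::optim(c(log(max(yy[1], 1e-6)), r0), sse,
                   control = list(maxit = 2000, reltol = 1e-14))
    })
    par <- fits[[which.min(vapply(fits, `[[`, numeric(1), "value"))]]$par
    C0 <- exp(par[1]); r <- par[2]
    if (r <= 0) next
    g <- C0 / r * (exp(r * tt) - 1)
    X <- cbind(1, g)
    beta <- solve(t(X) %*% X, t(X) %*% fluor[idx])
    if (beta[2] > best) best <- beta[2]
  }
  if (is.finite(best)) best else NA_real_
}

# Direct Gaussian kernel sum.
oracle_kde <- function(values, bw, x) {
  vapply(x, function(g) mean(exp(-(g - values)^2 / (2 * bw^2)) /
                               (bw * sqrt(2 * pi))), numeric(1))
}

# Brute-force peak rule: strict local maxima of the direct kernel sum on a
# dense grid, keep peaks >= 50% of the tallest, return the largest location.
oracle_no_burden <- function(values, bw, n_grid = 4001) {
  x <- seq(min(values) - 4 * bw, max(values) + 4 * bw, length.out = n_grid)
  y <- oracle_kde(values, bw, x)
  peaks <- which(diff(sign(diff(y))) == -2) + 1
  if (!length(peaks)) return(x[which.max(y)])
  keep <- y[peaks] >= 0.5 * max(y[peaks])
  max(x[peaks[keep]])
}

# Step-up BH from the definition.
oracle_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- p[o] * n / seq_len(n)
  adj <- rev(cummin(rev(adj)))
  out <- numeric(n)
  out[o] <- pmin(adj, 1)
  out
}

# Brute-force anchored Deming slope by 1-D minimisation of the objective.
oracle_deming_slope <- function(x, y, anchor = c(1, 1), lambda = 1) {
  u <- x - anchor[1]; v <- y - anchor[2]
  obj <- function(m) sum((v - m * u)^2) / (lambda + m^2)
  stats::optimize(obj, c(-50, 50), tol = 1e-12)$minimum
}

# Quick anchored capacity line for tests that need a known true line.
known_line <- function(slope = 1, anchor = c(1, 1)) {
  structure(list(slope = slope, anchor = anchor, lambda = 1, n = 0,
                 objective = 0, points = NULL), class = "capacity_line")
}
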