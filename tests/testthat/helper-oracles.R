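# Independent oracles for the mixed-model engine: dense-matrix likelihood
# evaluations and brute-force optimisation, sharing no code with the
# package's profiled implementation.

dense_V <- function(g, s2u, s2e) {
  g <- as.integer(factor(g))
  Z <- outer(g, sort(unique(g)), "==") * 1
  s2e * diag(length(g)) + s2u * tcrossprod(Z)
}

# Harville restricted log-likelihood, beta profiled out by GLS.
dense_reml_loglik <- function(y, X, g, s2u, s2e) {
  V <- dense_V(g, s2u, s2e)
  Vi <- solve(V)
  XtViX <- t(X) %*% Vi %*% X
  beta <- solve(XtViX, t(X) %*% Vi %*% y)
  r <- y - X %*% beta
  n <- length(y); p <- ncol(X)
  as.numeric(-0.5 * (determinant(V)$modulus + determinant(XtViX)$modulus +
                       t(r) %*% Vi %*% r + (n - p) * log(2 * pi)))
}

dense_ml_loglik <- function(y, X, g, beta, s2u, s2e) {
  V <- dense_V(g, s2u, s2e)
  r <- y - X %*% beta
  as.numeric(-0.5 * (length(y) * log(2 * pi) + determinant(V)$modulus +
                       t(r) %*% solve(V) %*% r))
}

# Brute-force REML: coarse grid over the two variance components followed by
# Nelder-Mead polish on the log scale.
brute_force_reml <- function(y, X, g) {
  vy <- stats::var(y)
  grid <- expand.grid(s2u = vy * c(0.001, 0.01, 0.05, 0.15, 0.4, 1),
                      s2e = vy * c(0.05, 0.2, 0.5, 0.8, 1.2))
  ll <- mapply(function(a, b) dense_reml_loglik(y, X, g, a, b),
               grid$s2u, grid$s2e)
  start <- log(unlist(grid[which.max(ll), ]))
  nm <- stats::optim(start, function(th)
    -dense_reml_loglik(y, X, g, exp(th[1]), exp(th[2])),
    method = "Nelder-Mead", control = list(maxit = 2000, reltol = 1e-12))
  polish <- stats::nlminb(nm$par, function(th)
    -dense_reml_loglik(y, X, g, exp(th[1]), exp(th[2])),
    control = list(rel.tol = 1e-14, abs.tol = 0, x.tol = 1e-12))
  polish$value <- polish$objective
  s2u <- unname(exp(polish$par[1])); s2e <- unname(exp(polish$par[2]))
  # boundary candidate
  ll0 <- dense_reml_loglik(y, X, g, 0, stats::optimize(function(s)
    dense_reml_loglik(y, X, g, 0, s), c(1e-6, 5 * vy), maximum = TRUE)$maximum)
  if (ll0 > -polish$value) {
    opt_s2e <- stats::optimize(function(s) dense_reml_loglik(y, X, g, 0, s),
                               c(1e-6, 5 * vy), maximum = TRUE)
    s2u <- 0; s2e <- opt_s2e$maximum
  }
  V <- dense_V(g, s2u, s2e)
  Vi <- solve(V)
  beta <- solve(t(X) %*% Vi %*% X, t(X) %*% Vi %*% y)
  list(loglik = dense_reml_loglik(y, X, g, s2u, s2e),
       s2u = s2u, s2e = s2e, beta = as.numeric(beta))
}

# Brute-force ML: direct joint optimisation over (beta, log s2u, log s2e).
brute_force_ml <- function(y, X, g) {
  p <- ncol(X)
  start <- c(stats::coef(stats::lm.fit(X, y)), log(stats::var(y) / 4),
             log(stats::var(y) / 2))
  polish <- stats::optim(start, function(th)
    -dense_ml_loglik(y, X, g, th[1:p], exp(th[p + 1]), exp(th[p + 2])),
    method = "Nelder-Mead", control = list(maxit = 5000, reltol = 1e-12))
  list(loglik = -polish$value, beta = polish$par[1:p],
       s2u = exp(polish$par[p + 1]), s2e = exp(polish$par[p + 2]))
}

# Balanced one-way ANOVA REML closed form: sigma2_e = MSW,
# sigma2_u = max(0, (MSB - MSW) / n_per_group).
anova_reml_closed_form <- function(y, g) {
  g <- factor(g)
  a <- nlevels(g)
  n <- length(y) / a
  gm <- tapply(y, g, mean)
  msb <- n * sum((gm - mean(y))^2) / (a - 1)
  msw <- sum((y - gm[g])^2) / (a * (n - 1))
  list(s2e = msw, s2u = max(0, (msb - msw) / n))
}

# Fixed-seed small mixed-model instance shared by oracle tests.
small_mlm_instance <- function(seed = 42, n_groups = 6, n = 60) {
  set.seed(seed)
  g <- rep(seq_len(n_groups), each = n / n_groups)
  x1 <- rnorm(n); x2 <- rnorm(n)
  y <- 1 + 0.5 * x1 - 0.3 * x2 + rnorm(n_groups, sd = 0.4)[g] +
    rnorm(n, sd = 0.8)
  list(data = data.frame(y = y, x1 = x1, x2 = x2, g = g),
       X = cbind("(Intercept)" = 1, x1 = x1, x2 = x2), y = y, g = g)
}
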